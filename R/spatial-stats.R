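#' Moran's I spatial autocorrelation
#'
#' Global Moran's I for one per-spot feature:
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with
#' `z = values - mean(values)` and `S0 = sum_ij w_ij`. Self-weights are
#' excluded (the diagonal of W is zeroed). Values near +1 indicate spatial
#' clustering, values near `-1/(n-1)` spatial randomness, and negative
#' values dispersion. Constant features are degenerate and raise an error.
#'
#' @param values numeric vector, one value per spot.
#' @param weights `spatial_weights` object or any (sparse) square weight
#'   matrix over the same spots.
#' @return list with `I` and `n`.
#' @export
morans_i <- function(values, weights) {
  W <- if (is(weights, "spatial_weights")) weights$W else weights
  n <- length(values)
  if (nrow(W) != n) stop("weights do not match the number of values")
  if (sd(values) == 0)
    stop("Moran's I is undefined for a constant feature (zero variance)")
  diag(W) <- 0
  W <- drop0(as(W, "CsparseMatrix"))
  S0 <- sum(W)
  if (S0 <= 0) stop("weight matrix has zero total weight")
  z <- values - mean(values)
  num <- as.numeric(t(z) %*% (W %*% z))
  I <- (n / S0) * num / sum(z^2)
  list(I = I, n = n)
}

#' Moran's I for every column of a matrix
#'
#' @param m spots x features matrix.
#' @inheritParams morans_i
#' @return data.frame with `feature` and `I`; constant columns get `NA`.
#' @export
morans_i_columns <- function(m, weights) {
  I <- vapply(seq_len(ncol(m)), function(j) {
    v <- as.numeric(m[, j])
    if (sd(v) == 0) return(NA_real_)
    morans_i(v, weights)$I
  }, numeric(1))
  data.frame(feature = colnames(m) %||% as.character(seq_len(ncol(m))),
             I = I, stringsAsFactors = FALSE)
}

#' Mean distance from each margin spot to the tumor
#'
#' For every margin-labeled spot, the mean Euclidean distance to its `k`
#' nearest tumor-region spots. Translation- and rotation-invariant.
#'
#' @param spots spot table with `region` labels including `tumor` and
#'   `margin`.
#' @param k number of nearest tumor spots to average over (default 5).
#' @return data.frame with `barcode` (margin spots) and `distance`.
#' @export
distance_to_tumor <- function(spots, k = 5) {
  if (is.null(spots$region)) stop("spot table has no region labels")
  tum <- spots[spots$region == "tumor", , drop = FALSE]
  mar <- spots[spots$region == "margin", , drop = FALSE]
  if (!nrow(tum)) stop("no tumor spots labeled")
  if (!nrow(mar)) stop("no margin spots labeled")
  if (nrow(tum) < k)
    stop("fewer tumor spots (", nrow(tum), ") than k = ", k)
  D <- cross_dist(cbind(mar$x, mar$y), cbind(tum$x, tum$y))
  d <- apply(D, 1, function(r) mean(sort(r)[seq_len(k)]))
  data.frame(barcode = mar$barcode, distance = d, stringsAsFactors = FALSE)
}

#' Log-log regression of margin burden on distance to tumor
#'
#' Ordinary least squares of `ln(burden)` on `ln(distance)` over margin
#' spots, modeling a power-law decay `burden ~ c * distance^slope` of
#' normalized mutational burden away from the tumor boundary. Spots with
#' nonpositive burden or distance are dropped (log undefined) and counted.
#' `r_squared` is the squared Pearson correlation of the fitted pairs.
#'
#' @param burden per-margin-spot normalized SNV burden (see
#'   [spot_burden()]).
#' @param distance per-margin-spot mean distance to tumor (see
#'   [distance_to_tumor()]).
#' @return list with `slope`, `intercept`, `r_squared`, `n` (spots used)
#'   and `n_dropped`.
#' @export
burden_distance_fit <- function(burden, distance) {
  if (length(burden) != length(distance))
    stop("burden and distance must be the same length")
  ok <- is.finite(burden) & is.finite(distance) & burden > 0 & distance > 0
  n_dropped <- sum(!ok)
  if (n_dropped)
    message(n_dropped, " spot(s) dropped from log-log fit (nonpositive burden or distance)")
  if (sum(ok) < 3) stop("fewer than 3 usable spots for the fit")
  lx <- log(distance[ok]); ly <- log(burden[ok])
  fit <- lm(ly ~ lx)
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = cor(lx, ly)^2,
       n = sum(ok), n_dropped = n_dropped)
}

#' Correlation of margin decay slopes with immune scores across sections
#'
#' Pearson correlation (with two-sided p value) between the per-section
#' decay slopes of the burden-distance regression and externally computed
#' per-section immune scores.
#'
#' @param slopes numeric vector, one decay slope per section.
#' @param immune_scores numeric vector of per-section immune scores.
#' @return list with `r`, `p` and `n`.
#' @export
slope_vs_immune <- function(slopes, immune_scores) {
  if (length(slopes) != length(immune_scores))
    stop("slopes and immune_scores must be the same length")
  if (length(slopes) < 3)
    stop("need at least 3 sections for a correlation with a p value")
  ct <- cor.test(slopes, immune_scores, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(slopes))
}

#' Expression-bin-controlled signature score
#'
#' Per-spot score of a gene set (e.g. a tumor-associated-macrophage
#' signature): mean expression of the signature genes minus the mean of a
#' control set drawn per expression bin. Genes are binned by average
#' expression into `n_bins` rank bins and `n_ctrl` controls are sampled
#' from the bin of each signature gene, so the control matches the
#' signature's expression strata.
#'
#' @param expression spots x genes matrix.
#' @param gene_set character vector of signature genes.
#' @param n_bins number of average-expression bins (default 25).
#' @param n_ctrl control genes sampled per signature gene (default 50).
#' @param seed RNG seed for control sampling.
#' @return named numeric vector of per-spot scores.
#' @export
signature_score <- function(expression, gene_set, n_bins = 25, n_ctrl = 50,
                            seed = 0L) {
  genes <- colnames(expression)
  gene_set <- intersect(gene_set, genes)
  if (!length(gene_set)) stop("none of the signature genes are in the matrix")
  gm <- Matrix::colMeans(expression)
  n_bins <- min(n_bins, length(gm))
  bins <- cut(rank(gm, ties.method = "first"), breaks = n_bins,
              labels = FALSE)
  names(bins) <- genes
  set.seed(seed)
  ctrl <- character(0)
  for (g in gene_set) {
    pool <- genes[bins == bins[g]]
    take <- if (length(pool) <= n_ctrl) pool else sample(pool, n_ctrl)
    ctrl <- c(ctrl, take)   # multiset: repeats across signature genes allowed
  }
  sig_mean <- Matrix::rowMeans(expression[, gene_set, drop = FALSE])
  ctrl_mean <- Matrix::rowMeans(expression[, ctrl, drop = FALSE])
  out <- as.numeric(sig_mean - ctrl_mean)
  names(out) <- rownames(expression)
  out
}

#' Correlation of per-spot burden with pathway scores
#'
#' Pearson correlation of the normalized per-spot SNV burden with each
#' pathway score column, sorted by decreasing correlation.
#'
#' @param burden per-spot normalized SNV burden.
#' @param pathway_scores spots x pathways numeric matrix.
#' @return data.frame with `pathway` and `r`.
#' @export
burden_pathway_correlation <- function(burden, pathway_scores) {
  m <- as.matrix(pathway_scores)
  if (nrow(m) != length(burden))
    stop("pathway scores and burden cover different numbers of spots")
  r <- vapply(seq_len(ncol(m)), function(j) {
    if (sd(m[, j]) == 0 || sd(burden) == 0) return(NA_real_)
    cor(burden, m[, j])
  }, numeric(1))
  out <- data.frame(pathway = colnames(m) %||% as.character(seq_len(ncol(m))),
                    r = r, stringsAsFactors = FALSE)
  out[order(-out$r), , drop = FALSE]
}

#' Chi-square association of SNV presence with tumor region
#'
#' Thin wrapper building the 2 x regions contingency table of SNV
#' presence/absence against spot region labels and applying the chi-square
#' test of independence.
#'
#' @param presence logical/0-1 vector of per-spot SNV presence.
#' @param region character vector of spot region labels.
#' @return list with `statistic`, `p` and the contingency `table`.
#' @export
region_snv_association <- function(presence, region) {
  if (length(presence) != length(region))
    stop("presence and region must be the same length")
  tab <- table(presence = as.integer(presence > 0), region = region)
  ct <- suppressWarnings(chisq.test(tab))
  list(statistic = unname(ct$statistic), p = ct$p.value, table = tab)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file (tab-separated: set name, description, genes...).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}
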