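#' Aggregate SNVs into fixed-width genomic windows
#'
#' Consolidates the raw unique-read counts of SNVs into genomic windows of
#' `window_size` bp. An SNV at (1-based) position `pos` falls in window
#' `floor(pos / window_size)`; windows are labeled `"chrom@index"` (e.g. a
#' locus at chr22:32,812,345 with 100-kb windows is in `"chr22@328"`).
#' Each SNV belongs to exactly one window and total counts are conserved.
#'
#' @param x `spot_snv_matrix` with raw unique-read counts.
#' @param window_size window width in bp (default 100000).
#' @return object of class `window_matrix`: list with `counts` (sparse
#'   spots x windows), `windows` (data.frame `chrom`, `index`, `label`),
#'   `spots`, and `smoothed` (NULL until [smooth_windows()]).
#' @export
window_aggregate <- function(x, window_size = 100000) {
  stopifnot(is(x, "spot_snv_matrix"))
  if (window_size < 1) stop("window_size must be >= 1")
  idx <- floor(x$snvs$pos / window_size)
  label <- paste0(x$snvs$chrom, "@", idx)
  fac <- factor(label, levels = unique(label))
  A <- sparseMatrix(i = seq_along(fac), j = as.integer(fac),
                    x = rep(1, length(fac)),
                    dims = c(length(fac), nlevels(fac)))
  counts <- x$counts %*% A
  colnames(counts) <- levels(fac)
  rownames(counts) <- rownames(x$counts)
  windows <- data.frame(
    chrom = x$snvs$chrom[!duplicated(fac)],
    index = idx[!duplicated(fac)],
    label = levels(fac),
    stringsAsFactors = FALSE
  )
  structure(list(counts = as(counts, "CsparseMatrix"), windows = windows,
                 spots = x$spots, snvs = x$snvs,
                 window_size = window_size, smoothed = NULL),
            class = "window_matrix")
}

#' @export
print.window_matrix <- function(x, ...) {
  cat(sprintf("window_matrix: %d spots x %d windows (%g bp)%s\n",
              nrow(x$counts), ncol(x$counts), x$window_size,
              if (is.null(x$smoothed)) "" else ", smoothed"))
  invisible(x)
}

#' Gaussian k-nearest-neighbor spatial weights
#'
#' Builds a spots x spots weight matrix from k-nearest-neighbor distances
#' with a Gaussian kernel, `W_ij = exp(-D_ij^2 / (2 alpha^2))` for j among
#' i's k nearest neighbors (union-symmetrized) and `W_ii = 1`; all other
#' entries are zero. `alpha` controls how quickly the influence of distant
#' neighbors is attenuated; the default is the mean k-NN distance of the
#' section.
#'
#' @param spots spot table with `x`, `y` coordinates.
#' @param k number of nearest neighbors (`< n_spots`).
#' @param alpha Gaussian bandwidth in coordinate units; `NULL` for the
#'   mean k-NN distance.
#' @return object of class `spatial_weights`: list with sparse `W`,
#'   `alpha` and `k`.
#' @export
spatial_weights <- function(spots, k = 6, alpha = NULL) {
  n <- nrow(spots)
  if (k >= n) stop("k must be smaller than the number of spots")
  if (!is.null(alpha) && alpha <= 0) stop("alpha must be positive")
  D <- as.matrix(dist(cbind(spots$x, spots$y)))
  nb_i <- integer(0); nb_j <- integer(0); nb_d <- numeric(0)
  knn_d <- numeric(n)
  for (i in seq_len(n)) {
    o <- order(D[i, ])
    o <- o[o != i][seq_len(k)]
    nb_i <- c(nb_i, rep(i, k)); nb_j <- c(nb_j, o)
    nb_d <- c(nb_d, D[i, o])
    knn_d[i] <- mean(D[i, o])
  }
  if (is.null(alpha)) alpha <- mean(knn_d)
  # union-symmetrize the neighbor relation
  ii <- c(nb_i, nb_j); jj <- c(nb_j, nb_i); dd <- c(nb_d, nb_d)
  key <- paste(ii, jj)
  keep <- !duplicated(key)
  w <- exp(-dd[keep]^2 / (2 * alpha^2))
  W <- sparseMatrix(i = c(ii[keep], seq_len(n)),
                    j = c(jj[keep], seq_len(n)),
                    x = c(w, rep(1, n)), dims = c(n, n),
                    dimnames = list(spots$barcode, spots$barcode))
  structure(list(W = W, alpha = alpha, k = k), class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %d spots, k = %d, alpha = %.4g\n",
              nrow(x$W), x$k, x$alpha))
  invisible(x)
}

#' Spatially smooth a window matrix
#'
#' Applies the Gaussian neighbor weights to the window counts,
#' `M_w = W x M`, spreading each spot's signal over its spatial
#' neighborhood. With `row_normalize = TRUE` the weights are scaled to row
#' sums of one, so a spatially constant column is left unchanged.
#'
#' @param wm `window_matrix`.
#' @param weights `spatial_weights` over the same spots.
#' @param row_normalize divide each row of W by its sum before the product.
#' @return `wm` with the `smoothed` slot filled.
#' @export
smooth_windows <- function(wm, weights, row_normalize = FALSE) {
  stopifnot(is(wm, "window_matrix"), is(weights, "spatial_weights"))
  W <- weights$W
  if (nrow(W) != nrow(wm$counts))
    stop("weights and window matrix cover different numbers of spots")
  if (row_normalize) {
    rs <- Matrix::rowSums(W)
    W <- Diagonal(x = 1 / rs) %*% W
  }
  wm$smoothed <- as(W %*% wm$counts, "CsparseMatrix")
  dimnames(wm$smoothed) <- dimnames(wm$counts)
  wm
}

#' Spatial correlation scores between windows
#'
#' For each window, spots below its `top_fraction` quantile of nonzero
#' smoothed signal are zeroed (keeping the most informative spots), then
#' the window-window score matrix is the cross-product of the masked
#' smoothed matrix, `W_corr = M_w' M_w`. Windows with fewer than two
#' nonzero spots get a zero row/column. The matrix is symmetric; the
#' diagonal (self-scores) is excluded downstream.
#'
#' @param wm smoothed `window_matrix`.
#' @param top_fraction fraction of top-signal spots retained per window
#'   (default 0.5).
#' @return dense symmetric matrix of window-window scores with window
#'   labels as dimnames.
#' @export
window_correlation <- function(wm, top_fraction = 0.5) {
  stopifnot(is(wm, "window_matrix"))
  if (is.null(wm$smoothed)) stop("smooth the window matrix first")
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  M <- as.matrix(wm$smoothed)
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    nz <- v > 0
    if (sum(nz) < 2) { M[, j] <- 0; next }
    thr <- quantile(v[nz], probs = 1 - top_fraction, names = FALSE)
    v[v < thr] <- 0
    M[, j] <- v
  }
  cc <- crossprod(M)
  dimnames(cc) <- list(colnames(wm$counts), colnames(wm$counts))
  cc
}

#' Build the window connectivity graph
#'
#' For each window, keeps its `top_fraction` highest-scoring partner
#' windows and converts scores to edge weights with a Gaussian decay on
#' the rank-normalized score distance `r = 1 - score / max_score` of that
#' row: `weight = exp(-r^2 / (2 decay_alpha^2))`. The result is a directed
#' weighted graph (each window chooses its own partners, so it may be
#' asymmetric).
#'
#' @param corr window x window score matrix from [window_correlation()].
#' @param top_fraction fraction of partners kept per window (default 0.5).
#' @param decay_alpha bandwidth of the Gaussian decay on normalized score
#'   distance (default 0.5).
#' @return directed weighted `igraph` graph whose vertices are window
#'   labels.
#' @export
build_group_graph <- function(corr, top_fraction = 0.5, decay_alpha = 0.5) {
  n <- nrow(corr)
  labels <- rownames(corr)
  edges <- list()
  for (i in seq_len(n)) {
    s <- corr[i, ]
    s[i] <- 0
    cand <- which(s > 0)
    if (!length(cand)) next
    keep_n <- max(1L, ceiling(top_fraction * length(cand)))
    cand <- cand[order(s[cand], decreasing = TRUE)][seq_len(keep_n)]
    mx <- max(s[cand])
    r <- 1 - s[cand] / mx
    w <- exp(-r^2 / (2 * decay_alpha^2))
    edges[[i]] <- data.frame(from = labels[i], to = labels[cand],
                             weight = w, stringsAsFactors = FALSE)
  }
  el <- do.call(rbind, edges)
  g <- igraph::graph_from_data_frame(
    el %||% data.frame(from = character(), to = character(),
                       weight = numeric()),
    directed = TRUE,
    vertices = data.frame(name = labels))
  g
}

#' Leiden SNV groups
#'
#' Runs Leiden community detection on the window connectivity graph (edge
#' weights as strengths) to partition windows into spatially coherent SNV
#' groups. The directed graph is union-collapsed to undirected (maximum
#' weight per pair) for the backend. Groups are ranked by summed
#' within-group edge weight and relabeled `0 .. G-1`; the run is
#' deterministic given `seed`.
#'
#' @param graph directed weighted graph from [build_group_graph()].
#' @param resolution Leiden resolution; larger values give more, smaller
#'   groups (default 5, suited to genome-scale window sets; see the
#'   methods vignette for guidance on small fixtures).
#' @param seed RNG seed for the backend.
#' @param objective `"modularity"` (default) or `"CPM"`.
#' @return list with `assignment` (named integer vector window -> group
#'   id), `sizes`, `resolution` and the undirected `graph` used.
#' @export
leiden_groups <- function(graph, resolution = 5.0, seed = 1L,
                          objective = c("modularity", "CPM")) {
  objective <- match.arg(objective)
  und <- igraph::as_undirected(graph, mode = "collapse",
                               edge.attr.comb = list(weight = "max"))
  set.seed(seed)
  cl <- igraph::cluster_leiden(und, objective_function = objective,
                               weights = igraph::E(und)$weight,
                               resolution = resolution, n_iterations = 10)
  memb <- igraph::membership(cl)
  # rank groups by summed within-group weight, ids 0..G-1
  el <- igraph::as_data_frame(und, what = "edges")
  gw <- tapply(el$weight * (memb[el$from] == memb[el$to]),
               memb[el$from], sum)
  all_g <- sort(unique(memb))
  wsum <- setNames(rep(0, length(all_g)), all_g)
  wsum[names(gw)] <- ifelse(is.na(gw), 0, gw)
  rank <- rank(-wsum, ties.method = "first") - 1L
  assignment <- setNames(as.integer(rank[as.character(memb)]), names(memb))
  list(assignment = assignment,
       sizes = table(assignment),
       resolution = resolution,
       graph = und)
}

#' Per-spot SNV group scores
#'
#' UMI-normalized group burden per spot:
#' `score[spot, g] = ln(sum_{w in g} M[spot, w] / U_spot + 1)`, where M is
#' the raw (unsmoothed) unique-read window count matrix and `U_spot` the
#' spot's total mRNA UMI.
#'
#' @param wm `window_matrix` (raw counts are used).
#' @param assignment named vector window label -> group id (from
#'   [leiden_groups()]).
#' @return dense matrix spots x groups, columns named `group_<id>`.
#' @export
group_scores <- function(wm, assignment) {
  stopifnot(is(wm, "window_matrix"))
  U <- wm$spots$total_umi
  if (any(U <= 0 & Matrix::rowSums(wm$counts) > 0))
    stop("total_umi is 0 for spot(s) with window signal")
  gids <- sort(unique(assignment))
  out <- matrix(0, nrow(wm$counts), length(gids),
                dimnames = list(rownames(wm$counts),
                                paste0("group_", gids)))
  for (gi in seq_along(gids)) {
    members <- names(assignment)[assignment == gids[gi]]
    members <- intersect(members, colnames(wm$counts))
    if (!length(members)) next
    s <- Matrix::rowSums(wm$counts[, members, drop = FALSE])
    out[, gi] <- ifelse(U > 0, log1p(s / U), 0)
  }
  out
}

#' Representative gene of an SNV window
#'
#' A window whose member SNVs are all intergenic has no representative
#' (`NA`). If all genic SNVs fall in one gene, that gene is chosen. With
#' several candidate genes, the gene whose expression profile across spots
#' correlates best (Pearson) with the window's raw count vector wins; ties
#' break toward the larger correlation, then the lexicographically smaller
#' gene id.
#'
#' @param wm `window_matrix` built from annotated SNVs (the stored SNV
#'   table must carry `gene` and `genomic_region`).
#' @param expression spots x genes matrix (needed only for multi-gene
#'   windows), rows aligned with `wm` spots.
#' @return named character vector window label -> gene (NA when
#'   intergenic-only).
#' @export
representative_gene <- function(wm, expression = NULL) {
  stopifnot(is(wm, "window_matrix"))
  snvs <- wm$snvs
  if (is.null(snvs$gene))
    stop("window matrix was built from unannotated SNVs")
  widx <- floor(snvs$pos / wm$window_size)
  wlabel <- paste0(snvs$chrom, "@", widx)
  out <- setNames(rep(NA_character_, ncol(wm$counts)), colnames(wm$counts))
  for (lab in colnames(wm$counts)) {
    genes <- snvs$gene[wlabel == lab & !is.na(snvs$gene) &
                         snvs$genomic_region != "intergenic"]
    genes <- sort(unique(genes))
    if (!length(genes)) next
    if (length(genes) == 1L) { out[lab] <- genes; next }
    if (is.null(expression))
      stop("multi-gene window ", lab,
           " needs an expression matrix to pick a representative")
    have <- genes[genes %in% colnames(expression)]
    if (!length(have)) next
    v <- as.numeric(wm$counts[, lab])
    rs <- vapply(have, function(g) {
      e <- as.numeric(expression[, g])
      if (sd(e) == 0 || sd(v) == 0) return(-Inf)
      cor(e, v)
    }, numeric(1))
    out[lab] <- have[order(-rs, have)][1]
  }
  out
}
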