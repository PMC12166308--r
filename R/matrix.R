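#' Spot-by-SNV count matrix
#'
#' Container tying a sparse spots x SNVs count matrix to its spot table and
#' SNV table. The `layer` records whether entries are raw UMI-deduplicated
#' read counts, binary presence calls, or UMI-normalized burden values.
#'
#' @param counts sparse matrix (spots x SNVs), rownames = barcodes,
#'   colnames = SNV ids.
#' @param spots spot table (see [read_spot_table()]).
#' @param snvs SNV table (see [read_filtered_vcf()]).
#' @param layer one of `"raw"`, `"binary"`, `"normalized"`.
#' @return object of class `spot_snv_matrix`.
#' @export
spot_snv_matrix <- function(counts, spots, snvs,
                            layer = c("raw", "binary", "normalized")) {
  layer <- match.arg(layer)
  counts <- as(counts, "CsparseMatrix")
  stopifnot(nrow(counts) == nrow(spots), ncol(counts) == nrow(snvs))
  if (any(counts@x < 0)) stop("counts must be nonnegative")
  if (layer == "binary" && length(counts@x) && !all(counts@x %in% c(0, 1)))
    stop("binary layer must contain only 0/1")
  structure(list(counts = counts, spots = spots, snvs = snvs, layer = layer),
            class = "spot_snv_matrix")
}

#' @export
print.spot_snv_matrix <- function(x, ...) {
  cat(sprintf("spot_snv_matrix: %d spots x %d SNVs [%s layer], %d nonzero\n",
              nrow(x$counts), ncol(x$counts), x$layer, length(x$counts@x)))
  invisible(x)
}

#' @export
dim.spot_snv_matrix <- function(x) dim(x$counts)

#' Build the raw spot-by-SNV matrix from read evidence
#'
#' Evidence rows are first deduplicated on the key
#' `(barcode, umi, chrom, pos)` so that PCR/optical duplicates of the same
#' molecule count once. Each retained unique read whose allele equals the
#' SNV's alternative base increments `counts[spot, snv]`; reads matching the
#' reference or a third base contribute nothing. Barcodes absent from the
#' spot table and loci absent from the call set are dropped, with counts
#' reported via `message()`.
#'
#' @param evidence data.frame from [read_evidence()].
#' @param snvs SNV table from [read_filtered_vcf()].
#' @param spots spot table.
#' @return `spot_snv_matrix` with the raw layer.
#' @export
build_spot_snv_matrix <- function(evidence, snvs, spots) {
  spots <- validate_spot_table(as.data.frame(spots))
  ev <- as.data.frame(evidence)
  ev$barcode <- as.character(ev$barcode)

  unknown_bc <- !(ev$barcode %in% spots$barcode)
  if (any(unknown_bc))
    message(sum(unknown_bc), " evidence rows dropped (barcode not in spot table)")
  ev <- ev[!unknown_bc, , drop = FALSE]

  loc_key <- paste(snvs$chrom, snvs$pos)
  unknown_loc <- !(paste(ev$chrom, ev$pos) %in% loc_key)
  if (any(unknown_loc))
    message(sum(unknown_loc), " evidence rows ignored (locus not in call set)")
  ev <- ev[!unknown_loc, , drop = FALSE]

  # UMI deduplication: one molecule per (barcode, umi, locus)
  dedup_key <- paste(ev$barcode, ev$umi, ev$chrom, ev$pos, sep = "\r")
  ev <- ev[!duplicated(dedup_key), , drop = FALSE]

  j <- match(paste(ev$chrom, ev$pos, ev$allele),
             paste(snvs$chrom, snvs$pos, snvs$alt))
  alt_match <- !is.na(j)
  ev <- ev[alt_match, , drop = FALSE]
  j <- j[alt_match]
  i <- match(ev$barcode, spots$barcode)

  counts <- sparseMatrix(i = i, j = j, x = rep(1, length(i)),
                         dims = c(nrow(spots), nrow(snvs)),
                         dimnames = list(spots$barcode, snv_id(snvs)))
  spot_snv_matrix(counts, spots, snvs, layer = "raw")
}

#' Aggregate spots into square bins
#'
#' Sums counts and total UMI within blocks of `bin_size x bin_size` lattice
#' positions (e.g. `bin_size = 100` produces Stereo-seq style bin100
#' blocks). The new spot id encodes the block indices
#' `(floor(x / bin_size), floor(y / bin_size))`; total counts are conserved.
#' Region labels, when present, are carried over by majority vote within
#' each block.
#'
#' @param x `spot_snv_matrix` (raw layer) on an integer lattice.
#' @param bin_size side of the square block, `>= 1`.
#' @return `spot_snv_matrix` on the binned lattice.
#' @export
aggregate_spot_bins <- function(x, bin_size) {
  stopifnot(is(x, "spot_snv_matrix"))
  if (length(bin_size) != 1L || !is.finite(bin_size) || bin_size < 1)
    stop("bin_size must be a single integer >= 1")
  bin_size <- as.integer(bin_size)
  sp <- x$spots
  if (is.null(sp$region)) sp$region <- "unassigned"
  bx <- floor(sp$x / bin_size)
  by <- floor(sp$y / bin_size)
  fac <- factor(paste(bx, by, sep = "_"))
  G <- sparseMatrix(i = seq_along(fac), j = as.integer(fac),
                    x = rep(1, length(fac)),
                    dims = c(length(fac), nlevels(fac)))
  counts <- Matrix::t(G) %*% x$counts
  majority_region <- vapply(split(sp$region, fac), function(r)
    names(sort(table(r), decreasing = TRUE))[1], character(1))
  new_spots <- data.frame(
    barcode = paste0("bin_", levels(fac)),
    x = as.vector(tapply(bx, fac, function(v) v[1])),
    y = as.vector(tapply(by, fac, function(v) v[1])),
    total_umi = as.vector(tapply(sp$total_umi, fac, sum)),
    region = majority_region,
    stringsAsFactors = FALSE
  )
  rownames(counts) <- new_spots$barcode
  colnames(counts) <- colnames(x$counts)
  spot_snv_matrix(counts, new_spots, x$snvs, layer = x$layer)
}

#' Effective-SNV filter
#'
#' An SNV is effective when its total unique-read support is at least
#' `min_unique_reads` and it is observed (count > 0) in at least
#' `min_spots` spots. Column order is preserved; the operation is
#' idempotent.
#'
#' @param x `spot_snv_matrix` with the raw layer.
#' @param min_unique_reads minimum total unique reads per SNV (default 20).
#' @param min_spots minimum number of spots carrying the SNV (default 5).
#' @return `spot_snv_matrix` restricted to effective SNVs.
#' @export
filter_effective <- function(x, min_unique_reads = 20, min_spots = 5) {
  stopifnot(is(x, "spot_snv_matrix"))
  if (min_unique_reads < 1 || min_spots < 1)
    stop("min_unique_reads and min_spots must both be >= 1")
  reads <- Matrix::colSums(x$counts)
  nspots <- Matrix::colSums(x$counts > 0)
  keep <- reads >= min_unique_reads & nspots >= min_spots
  spot_snv_matrix(x$counts[, keep, drop = FALSE], x$spots,
                  x$snvs[keep, , drop = FALSE], layer = x$layer)
}

#' Binarize a count matrix
#'
#' Converts raw counts to presence/absence: an entry is 1 iff the raw count
#' is positive. Idempotent on binary input.
#'
#' @param x `spot_snv_matrix`.
#' @return `spot_snv_matrix` with the binary layer.
#' @export
binarize <- function(x) {
  stopifnot(is(x, "spot_snv_matrix"))
  b <- drop0(x$counts)
  b@x <- rep(1, length(b@x))
  spot_snv_matrix(b, x$spots, x$snvs, layer = "binary")
}

#' UMI-normalize SNV presence against per-spot sequencing depth
#'
#' For SNV i in a given spot with (binary) count s and total mRNA UMI U,
#' the normalized value is `ln(s / U + 1)`, removing the dependence of SNV
#' detection on per-spot sequencing depth. By default the input is
#' binarized first (presence/absence is what is normalized); set
#' `use_raw = TRUE` to normalize raw unique-read counts instead.
#'
#' @param x `spot_snv_matrix`.
#' @param use_raw normalize raw counts rather than presence calls.
#' @return `spot_snv_matrix` with the normalized layer.
#' @export
normalize_snv <- function(x, use_raw = FALSE) {
  stopifnot(is(x, "spot_snv_matrix"))
  if (!use_raw && x$layer != "binary") x <- binarize(x)
  U <- x$spots$total_umi
  bad <- U <= 0 & Matrix::rowSums(x$counts) > 0
  if (any(bad))
    stop("cannot normalize: total_umi is 0 for spot(s) with SNV signal: ",
         paste(head(x$spots$barcode[bad], 5), collapse = ", "))
  scale <- ifelse(U > 0, 1 / U, 0)
  n <- Diagonal(x = scale) %*% x$counts
  n <- as(n, "CsparseMatrix")
  n@x <- log1p(n@x)   # log1p(0) = 0, so sparsity is preserved
  dimnames(n) <- dimnames(x$counts)
  spot_snv_matrix(n, x$spots, x$snvs, layer = "normalized")
}

#' Per-spot normalized SNV burden
#'
#' The scalar per-spot mutational burden `ln(sum_i s_i / U + 1)` where
#' `s_i` are the (binary, unless `use_raw`) SNV counts of the spot and `U`
#' its total mRNA UMI.
#'
#' @inheritParams normalize_snv
#' @return named numeric vector, one value per spot.
#' @export
spot_burden <- function(x, use_raw = FALSE) {
  stopifnot(is(x, "spot_snv_matrix"))
  if (!use_raw && x$layer != "binary") x <- binarize(x)
  U <- x$spots$total_umi
  s <- Matrix::rowSums(x$counts)
  bad <- U <= 0 & s > 0
  if (any(bad))
    stop("cannot normalize burden: total_umi is 0 for spot(s) with SNV signal: ",
         paste(head(x$spots$barcode[bad], 5), collapse = ", "))
  out <- ifelse(U > 0, log1p(s / U), 0)
  names(out) <- x$spots$barcode
  out
}
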