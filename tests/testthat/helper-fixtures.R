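# Small in-code fixture builders shared by the tests.

# a spot table on given coordinates (or a k x k lattice)
make_spots <- function(n = NULL, coords = NULL, umi = 100,
                       region = "unassigned") {
  if (is.null(coords)) {
    k <- ceiling(sqrt(n))
    coords <- expand.grid(x = 0:(k - 1), y = 0:(k - 1))[seq_len(n), ]
  }
  n <- nrow(coords)
  data.frame(barcode = paste0("b", seq_len(n)),
             x = coords$x, y = coords$y,
             total_umi = rep_len(umi, n),
             region = rep_len(region, n),
             stringsAsFactors = FALSE)
}

# an SNV table with arbitrary loci
make_snvs <- function(n, chrom = "chr1", pos = NULL) {
  pos <- pos %||% (seq_len(n) * 1000L)
  sv <- data.frame(chrom = rep_len(chrom, n), pos = pos,
                   ref = rep_len("A", n), alt = rep_len("G", n),
                   filter = "PASS", stringsAsFactors = FALSE)
  sv$snv_id <- sprintf("%s_%s:%s>%s", sv$chrom, sv$pos, sv$ref, sv$alt)
  sv
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# spot_snv_matrix from a dense count matrix
make_ssm <- function(counts, umi = 100, layer = "raw", spots = NULL,
                     snvs = NULL) {
  counts <- as.matrix(counts)
  spots <- spots %||% make_spots(n = nrow(counts), umi = umi)
  snvs <- snvs %||% make_snvs(ncol(counts))
  m <- Matrix::Matrix(counts, sparse = TRUE)
  dimnames(m) <- list(spots$barcode, snvs$snv_id)
  spot_snv_matrix(m, spots, snvs, layer = layer)
}

# write a VCF from FILTER strings (one biallelic SNV record each)
write_filter_vcf <- function(filters, path, alt = NULL) {
  alt <- alt %||% rep("G", length(filters))
  lines <- c("##fileformat=VCFv4.2",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
             sprintf("chr1\t%d\t.\tA\t%s\t.\t%s\t.",
                     seq_along(filters) * 100L, alt, filters))
  writeLines(lines, path)
  path
}

# rook-adjacency binary weight matrix on an nr x nc lattice
rook_weights <- function(nr, nc) {
  idx <- function(r, c) (c - 1) * nr + r
  i <- integer(0); j <- integer(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (r < nr) { i <- c(i, idx(r, c)); j <- c(j, idx(r + 1, c)) }
    if (c < nc) { i <- c(i, idx(r, c)); j <- c(j, idx(r, c + 1)) }
  }
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                       dims = c(nr * nc, nr * nc))
}

# O(n^2) double-loop Moran's I oracle, independent of the implementation
moran_brute <- function(values, W) {
  W <- as.matrix(W)
  diag(W) <- 0
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}
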