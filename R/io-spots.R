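#' Read a spot table
#'
#' Reads the per-spot metadata of one spatial section: barcode, lattice
#' coordinates, total mRNA UMI count and (optionally) a region label in
#' `{tumor, margin, normal, unassigned}`.
#'
#' @param path TSV file with header columns `barcode`, `x`, `y`, `total_umi`
#'   and optionally `region`.
#' @return A data.frame with one row per spot. Barcodes are checked for
#'   uniqueness, coordinates for finiteness and `total_umi` for
#'   nonnegativity.
#' @export
read_spot_table <- function(path) {
  df <- as.data.frame(fread(path, sep = "\t", header = TRUE))
  validate_spot_table(df)
}

#' @rdname read_spot_table
#' @param spots spot table data.frame
#' @export
write_spot_table <- function(spots, path) {
  fwrite(spots, path, sep = "\t")
  invisible(path)
}

validate_spot_table <- function(df) {
  need <- c("barcode", "x", "y", "total_umi")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("spot table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$barcode))
    stop("spot barcodes must be unique")
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop("spot coordinates must be finite")
  if (any(df$total_umi < 0))
    stop("total_umi must be nonnegative")
  if (is.null(df$region)) df$region <- "unassigned"
  bad <- setdiff(unique(df$region), c("tumor", "margin", "normal", "unassigned"))
  if (length(bad))
    stop("unknown region label(s): ", paste(bad, collapse = ", "))
  df$barcode <- as.character(df$barcode)
  df
}

#' Read a per-read SNV evidence table
#'
#' One row per aligned read overlapping a candidate SNV locus, before UMI
#' deduplication.
#'
#' @param path TSV file with header columns `read_id`, `barcode`, `umi`,
#'   `chrom`, `pos`, `allele`.
#' @return data.frame of evidence rows.
#' @export
read_evidence <- function(path) {
  df <- as.data.frame(fread(path, sep = "\t", header = TRUE,
                            colClasses = list(character = c("barcode", "umi", "chrom", "allele"))))
  need <- c("read_id", "barcode", "umi", "chrom", "pos", "allele")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("evidence table is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_evidence
#' @param evidence evidence data.frame
#' @export
write_evidence <- function(evidence, path) {
  fwrite(evidence, path, sep = "\t")
  invisible(path)
}

#' Read or write a sparse expression matrix in MatrixMarket form
#'
#' The on-disk layout is a directory holding `matrix.mtx` (coordinate
#' MatrixMarket, spots as rows), `barcodes.tsv` (row names) and
#' `features.tsv` (column names).
#'
#' @param dir directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv`.
#' @return `read_expression_matrix`: a `dgCMatrix`, spots x genes, with
#'   dimnames from the barcode and feature files.
#' @export
read_expression_matrix <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("no matrix.mtx under ", dir)
  m <- as(Matrix::readMM(mtx), "CsparseMatrix")
  if (nrow(m) == 0L || ncol(m) == 0L)
    stop("expression matrix has a zero dimension (", nrow(m), " x ", ncol(m), ")")
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  features <- readLines(file.path(dir, "features.tsv"))
  if (length(barcodes) != nrow(m))
    stop("barcodes.tsv has ", length(barcodes), " entries but matrix has ",
         nrow(m), " rows")
  if (length(features) != ncol(m))
    stop("features.tsv has ", length(features), " entries but matrix has ",
         ncol(m), " columns")
  dimnames(m) <- list(barcodes, features)
  m
}

#' @rdname read_expression_matrix
#' @param m sparse matrix (spots x genes) with dimnames
#' @export
write_expression_matrix <- function(m, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(as(m, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(m), file.path(dir, "features.tsv"))
  invisible(dir)
}
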