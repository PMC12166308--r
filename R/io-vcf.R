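#' Default Mutect2 FILTER tags treated as disqualifying
#'
#' Records whose FILTER column carries any of these tags are discarded when
#' reading a somatic VCF: `weak_evidence`, `germline`, `strand_bias`,
#' `slippage`, `contamination`, `panel_of_normals`.
#'
#' @return character vector of tag names.
#' @export
mutect_excluded_tags <- function() {
  c("weak_evidence", "germline", "strand_bias", "slippage",
    "contamination", "panel_of_normals")
}

#' Read and filter a somatic VCF
#'
#' Parses a VCF 4.x file and keeps biallelic SNV records whose FILTER column
#' contains none of the excluded tags. `PASS` (and `.`) records are always
#' retained; records with other, non-excluded tags (e.g. `clustered_events`)
#' are kept. Multiallelic records are split and each alternative allele is
#' judged separately; only single-base substitutions survive.
#'
#' @param path VCF file (plain text).
#' @param excluded_tags character vector of disqualifying FILTER tags;
#'   defaults to [mutect_excluded_tags()].
#' @return data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `filter` and `snv_id`.
#' @export
read_filtered_vcf <- function(path, excluded_tags = mutect_excluded_tags()) {
  if (!file.exists(path)) stop("no such VCF file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr))
    stop("malformed VCF: no #CHROM header line in ", path)
  cols <- strsplit(sub("^#", "", lines[hdr[1]]), "\t")[[1]]
  if (!"FILTER" %in% cols)
    stop("format error: VCF header has no FILTER column")
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf < 7)
      stop("malformed VCF record at line ", i, ": only ", nf, " fields")
  }
  if (!length(body)) {
    return(empty_snv_table())
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) return(empty_snv_table())
  filt <- ifelse(is.na(fix$FILTER), ".", fix$FILTER)
  tags <- strsplit(filt, ";", fixed = TRUE)
  drop <- vapply(tags, function(t) any(t %in% excluded_tags), logical(1))
  fix <- fix[!drop, , drop = FALSE]
  if (!nrow(fix)) return(empty_snv_table())
  # split multiallelic ALTs; judge each allele separately
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  out <- data.frame(
    chrom  = rep(fix$CHROM, n_alt),
    pos    = as.integer(rep(fix$POS, n_alt)),
    ref    = rep(fix$REF, n_alt),
    alt    = unlist(alts),
    filter = ifelse(rep(is.na(fix$FILTER), n_alt), ".", rep(fix$FILTER, n_alt)),
    stringsAsFactors = FALSE
  )
  bases <- c("A", "C", "G", "T")
  keep <- nchar(out$ref) == 1L & nchar(out$alt) == 1L &
    out$ref %in% bases & out$alt %in% bases & out$ref != out$alt
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out$snv_id <- snv_id(out)
  out
}

empty_snv_table <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), filter = character(), snv_id = character(),
             stringsAsFactors = FALSE)
}

#' Write a minimal somatic VCF
#'
#' Emits a VCF 4.2 file with CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO columns;
#' used by the synthetic-section generator and for exporting filtered call
#' sets.
#'
#' @param snvs data.frame with `chrom`, `pos`, `ref`, `alt` and optionally
#'   `filter` (default `PASS`).
#' @param path output file.
#' @export
write_vcf <- function(snvs, path) {
  filt <- snvs$filter %||% rep("PASS", nrow(snvs))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(snvs))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.",
                       snvs$chrom, as.integer(snvs$pos), snvs$ref, snvs$alt,
                       filt), con)
  invisible(path)
}
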