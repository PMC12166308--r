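#' Mutant amino-acid context around a nonsynonymous SNV
#'
#' Translates the transcript CDS and takes up to 15 residues on each side
#' of the mutated residue (a window of at most 31 aa, truncated only at
#' the protein boundaries). The mutant context carries the substituted
#' residue at `center_index` (0-based); wild-type and mutant contexts
#' differ at exactly that position.
#'
#' @param snv one annotated SNV row with `transcript`, `effect`
#'   (`"nonsynonymous"`), `aa_pos`, `aa_ref`, `aa_alt` (see
#'   [annotate_snvs()]).
#' @param cds_seq `DNAStringSet` of CDS sequences keyed by transcript id
#'   (or a FASTA path).
#' @param flank residues kept on each side of the mutation (default 15).
#' @return list with `wt_context`, `mut_context`, `center_index`
#'   (0-based), `gene`, `snv_id` and `aa_change`.
#' @export
extract_context <- function(snv, cds_seq, flank = 15) {
  if (is.character(cds_seq) && length(cds_seq) == 1L)
    cds_seq <- Biostrings::readDNAStringSet(cds_seq)
  if (is.na(snv$effect) || snv$effect != "nonsynonymous")
    stop("context extraction requires a nonsynonymous SNV")
  tx <- snv$transcript
  if (!tx %in% names(cds_seq)) stop("no CDS sequence for transcript ", tx)
  s <- as.character(cds_seq[[tx]])
  if (nchar(s) %% 3 != 0) {
    warning("CDS length of ", tx, " is not a multiple of 3; using the longest in-frame prefix")
    s <- substr(s, 1, 3 * (nchar(s) %/% 3))
  }
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
  prot <- sub("\\*$", "", prot)   # drop the terminal stop
  p <- snv$aa_pos
  if (p < 1 || p > nchar(prot))
    stop("amino-acid position ", p, " outside protein of length ", nchar(prot))
  wt_res <- substr(prot, p, p)
  if (wt_res != snv$aa_ref)
    stop("annotation mismatch: protein has ", wt_res, " at position ", p,
         ", annotation says ", snv$aa_ref)
  from <- max(1L, p - flank)
  to <- min(nchar(prot), p + flank)
  wt <- substr(prot, from, to)
  mut <- wt
  center <- p - from   # 0-based
  substr(mut, center + 1, center + 1) <- snv$aa_alt
  list(wt_context = wt, mut_context = mut, center_index = center,
       gene = snv$gene %||% NA_character_,
       snv_id = snv$snv_id %||% NA_character_,
       aa_change = paste0(snv$aa_ref, p, snv$aa_alt))
}

#' Enumerate mutant peptides from a context
#'
#' Sliding windows of length `kmin..kmax` over the mutant context; every
#' returned peptide covers the mutated residue. For a full interior
#' context (31 aa with the mutation centered) this yields
#' `sum(kmin:kmax)` peptides (92 for 8-15-mers). Sequence-identical
#' peptides arising from distinct offsets are kept once, with all offsets
#' recorded.
#'
#' @param context list from [extract_context()].
#' @param kmin,kmax peptide length range (defaults 8 and 15).
#' @return data.frame with `sequence`, `length`, `start` (0-based offset
#'   in the context; first offset when duplicated), `offsets`
#'   (comma-separated), `gene`, `snv_id`, `aa_change`.
#' @export
enumerate_peptides <- function(context, kmin = 8, kmax = 15) {
  if (kmin < 1 || kmax < kmin) stop("need 1 <= kmin <= kmax")
  ctx <- context$mut_context
  L <- nchar(ctx)
  c1 <- context$center_index + 1   # 1-based center
  seqs <- character(0); lens <- integer(0); starts <- integer(0)
  for (k in kmin:kmax) {
    if (k > L) next
    for (s in max(1L, c1 - k + 1L):min(L - k + 1L, c1)) {
      seqs <- c(seqs, substr(ctx, s, s + k - 1L))
      lens <- c(lens, k)
      starts <- c(starts, s - 1L)
    }
  }
  if (!length(seqs)) {
    return(data.frame(sequence = character(), length = integer(),
                      start = integer(), offsets = character(),
                      gene = character(), snv_id = character(),
                      aa_change = character(), stringsAsFactors = FALSE))
  }
  offsets <- vapply(split(starts, seqs)[unique(seqs)],
                    function(o) paste(o, collapse = ","), character(1))
  first <- !duplicated(seqs)
  data.frame(sequence = seqs[first], length = lens[first],
             start = starts[first],
             offsets = unname(offsets[seqs[first]]),
             gene = context$gene, snv_id = context$snv_id,
             aa_change = context$aa_change,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the normal-peptide exclusion index
#'
#' Collects every `kmin..kmax`-mer of the translated reference CDS
#' proteome, plus peptides from user-supplied healthy-ligand lists (plain
#' text, one peptide per line), into an exact-membership index used to
#' discard mutant peptides that also occur in normal proteins.
#'
#' @param cds_seq `DNAStringSet` of reference CDS sequences (or FASTA
#'   path).
#' @param ligand_files character vector of plain-text peptide list files
#'   (may be empty).
#' @param kmin,kmax k-mer length range (defaults 8 and 15).
#' @return object of class `peptide_index` holding the proteome k-mer set
#'   and the ligand set.
#' @export
build_exclusion_index <- function(cds_seq, ligand_files = character(0),
                                  kmin = 8, kmax = 15) {
  if (is.character(cds_seq) && length(cds_seq) == 1L)
    cds_seq <- Biostrings::readDNAStringSet(cds_seq)
  prots <- vapply(seq_along(cds_seq), function(i) {
    s <- as.character(cds_seq[[i]])
    s <- substr(s, 1, 3 * (nchar(s) %/% 3))
    sub("\\*$", "", as.character(Biostrings::translate(Biostrings::DNAString(s))))
  }, character(1))
  kmers <- unlist(lapply(prots, function(p) {
    L <- nchar(p)
    unlist(lapply(kmin:kmax, function(k) {
      if (k > L) return(character(0))
      substring(p, 1:(L - k + 1), k:L)
    }))
  }))
  ligands <- character(0)
  for (f in ligand_files) ligands <- c(ligands, readLines(f))
  ligands <- ligands[nzchar(ligands)]
  structure(list(proteome = unique(kmers), ligands = unique(ligands),
                 kmin = kmin, kmax = kmax, n_proteins = length(prots)),
            class = "peptide_index")
}

#' @export
print.peptide_index <- function(x, ...) {
  cat(sprintf("peptide_index: %d proteome %d-%d-mers from %d proteins, %d ligand peptides\n",
              length(x$proteome), x$kmin, x$kmax, x$n_proteins,
              length(x$ligands)))
  invisible(x)
}

#' Filter mutant peptides against normal peptides
#'
#' Drops peptides found in the normal-proteome k-mer set or in the
#' healthy-ligand lists (exact string match); membership in known-epitope
#' databases is annotated but does not drop a peptide. Output is sorted
#' by gene, then sequence.
#'
#' @param peptides data.frame from [enumerate_peptides()] (rows from
#'   several contexts may be concatenated).
#' @param index `peptide_index` from [build_exclusion_index()].
#' @param known_epitope_files plain-text peptide lists of known
#'   HLA-presented epitopes (annotation only).
#' @return the surviving rows with added logical columns
#'   `in_normal_proteome`, `in_healthy_ligandome` (all FALSE by
#'   construction) and `in_known_epitope_db`.
#' @export
filter_candidates <- function(peptides, index,
                              known_epitope_files = character(0)) {
  stopifnot(is(index, "peptide_index"))
  known <- character(0)
  for (f in known_epitope_files) known <- c(known, readLines(f))
  known <- known[nzchar(known)]
  in_prot <- peptides$sequence %in% index$proteome
  in_lig <- peptides$sequence %in% index$ligands
  out <- peptides[!in_prot & !in_lig, , drop = FALSE]
  out$in_normal_proteome <- rep(FALSE, nrow(out))
  out$in_healthy_ligandome <- rep(FALSE, nrow(out))
  out$in_known_epitope_db <- out$sequence %in% known
  out <- out[order(out$gene, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-sample peptide sharing table
#'
#' Union of candidate peptides across samples as rows, presence per
#' sample as columns, sorted by the number of samples sharing each
#' peptide (descending), then by peptide.
#'
#' @param per_sample named list, sample -> character vector of peptides.
#' @return logical matrix peptides x samples.
#' @export
sharing_table <- function(per_sample) {
  if (!length(per_sample)) return(matrix(logical(0), 0, 0))
  all_p <- sort(unique(unlist(per_sample)))
  m <- vapply(per_sample, function(p) all_p %in% p,
              logical(length(all_p)))
  m <- matrix(m, nrow = length(all_p),
              dimnames = list(all_p, names(per_sample)))
  m[order(-rowSums(m), rownames(m)), , drop = FALSE]
}

#' Export candidate peptides for external HLA tools
#'
#' Writes a FASTA of peptide sequences with structured headers
#' `gene|snv_id|length|start` and a TSV with all columns and flags, ready
#' for downstream HLA typing / binding-affinity prediction.
#'
#' @param candidates data.frame from [filter_candidates()].
#' @param fasta_path,tsv_path output files.
#' @return invisibly, the FASTA path.
#' @export
export_for_hla_tools <- function(candidates, fasta_path, tsv_path) {
  con <- file(fasta_path, "w")
  if (nrow(candidates)) {
    hdr <- sprintf(">%s|%s|%d|%d", candidates$gene, candidates$snv_id,
                   candidates$length, candidates$start)
    writeLines(as.vector(rbind(hdr, candidates$sequence)), con)
  }
  close(con)
  fwrite(candidates, tsv_path, sep = "\t")
  invisible(fasta_path)
}

#' Read back an exported peptide FASTA
#'
#' @param fasta_path FASTA written by [export_for_hla_tools()].
#' @return data.frame with `gene`, `snv_id`, `length`, `start`,
#'   `sequence` parsed from the headers.
#' @export
read_peptide_fasta <- function(fasta_path) {
  lines <- readLines(fasta_path)
  if (!length(lines)) {
    return(data.frame(gene = character(), snv_id = character(),
                      length = integer(), start = integer(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  hdr <- lines[startsWith(lines, ">")]
  seqs <- lines[!startsWith(lines, ">")]
  f <- strsplit(sub("^>", "", hdr), "|", fixed = TRUE)
  data.frame(gene = vapply(f, `[`, "", 1),
             snv_id = vapply(f, `[`, "", 2),
             length = as.integer(vapply(f, `[`, "", 3)),
             start = as.integer(vapply(f, `[`, "", 4)),
             sequence = seqs, stringsAsFactors = FALSE)
}
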