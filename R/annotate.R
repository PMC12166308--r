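#' Annotate SNVs with genomic region and coding effect
#'
#' Assigns each SNV a genomic region by interval overlap with precedence
#' `exonic (CDS) > UTR5/UTR3 > splicing > intronic > ncRNA > intergenic`,
#' using 1-based closed intervals throughout (VCF convention). For exonic
#' SNVs the codon containing the position is looked up in the transcript
#' CDS (reverse-complemented arithmetic for minus-strand transcripts) and
#' the amino-acid effect derived from the standard genetic code.
#'
#' Splice sites are the two intronic bases flanking each exon boundary.
#' If the SNV reference base disagrees with the CDS base at that position a
#' warning is raised and the effect is recorded as `"unknown"`.
#'
#' @param snvs SNV table from [read_filtered_vcf()].
#' @param gtf_path GTF file with `gene`, `transcript`, `exon`, `CDS` and
#'   `five_prime_utr` / `three_prime_utr` features; attributes must include
#'   `gene_id`, `transcript_id` and `gene_biotype`.
#' @param cds_path FASTA of CDS sequences keyed by `transcript_id`, in
#'   coding orientation.
#' @return the input table with added columns `genomic_region`, `gene`,
#'   `transcript`, `effect`, `aa_ref`, `aa_pos`, `aa_alt` and `aa_change`
#'   (e.g. `"G12D"`).
#' @export
annotate_snvs <- function(snvs, gtf_path, cds_path) {
  gtf <- rtracklayer::import(gtf_path, format = "gtf")
  cds_seq <- Biostrings::readDNAStringSet(cds_path)
  names(cds_seq) <- sub("\\s.*$", "", names(cds_seq))

  biotype <- S4Vectors::mcols(gtf)$gene_biotype
  if (is.null(biotype)) biotype <- rep("protein_coding", length(gtf))
  coding <- !is.na(biotype) & biotype == "protein_coding"
  type <- S4Vectors::mcols(gtf)$type

  cds_gr   <- gtf[type == "CDS" & coding]
  utr5_gr  <- gtf[type == "five_prime_utr"]
  utr3_gr  <- gtf[type == "three_prime_utr"]
  exon_cod <- gtf[type == "exon" & coding]
  exon_nc  <- gtf[type == "exon" & !coding]
  tx_cod   <- gtf[type == "transcript" & coding]
  tx_nc    <- gtf[type == "transcript" & !coding]
  # splice sites: 2 intronic bases on each side of internal exon boundaries
  splice_gr <- splice_sites(exon_cod, tx_cod)

  loci <- GenomicRanges::GRanges(snvs$chrom,
                                 IRanges::IRanges(snvs$pos, snvs$pos))

  hit <- function(gr) IRanges::overlapsAny(loci, gr, ignore.strand = TRUE)
  in_cds   <- hit(cds_gr)
  in_utr5  <- hit(utr5_gr)
  in_utr3  <- hit(utr3_gr)
  in_spl   <- hit(splice_gr)
  in_tx    <- hit(tx_cod)
  in_nc    <- hit(exon_nc) | hit(tx_nc)

  region <- rep("intergenic", nrow(snvs))
  region[in_nc] <- "ncRNA"
  region[in_tx] <- "intronic"
  region[in_spl] <- "splicing"
  region[in_utr3] <- "UTR3"
  region[in_utr5] <- "UTR5"
  region[in_cds] <- "exonic"

  out <- snvs
  out$genomic_region <- region
  out$gene <- NA_character_
  out$transcript <- NA_character_
  out$effect <- NA_character_
  out$aa_ref <- NA_character_
  out$aa_pos <- NA_integer_
  out$aa_alt <- NA_character_

  # gene attribution for any genic location
  genic <- region != "intergenic"
  if (any(genic)) {
    tx_all <- suppressWarnings(c(tx_cod, tx_nc))
    ov <- GenomicRanges::findOverlaps(loci[genic], tx_all, ignore.strand = TRUE)
    first <- !duplicated(S4Vectors::queryHits(ov))
    gi <- which(genic)[S4Vectors::queryHits(ov)[first]]
    gene_id <- S4Vectors::mcols(tx_all)$gene_name %||%
      S4Vectors::mcols(tx_all)$gene_id
    gene_id <- ifelse(is.na(gene_id), S4Vectors::mcols(tx_all)$gene_id, gene_id)
    out$gene[gi] <- gene_id[S4Vectors::subjectHits(ov)[first]]
  }

  for (i in which(in_cds)) {
    eff <- coding_effect(snvs$chrom[i], snvs$pos[i], snvs$ref[i], snvs$alt[i],
                         cds_gr, cds_seq)
    out$transcript[i] <- eff$transcript
    out$effect[i] <- eff$effect
    out$aa_ref[i] <- eff$aa_ref
    out$aa_pos[i] <- eff$aa_pos
    out$aa_alt[i] <- eff$aa_alt
  }
  out$aa_change <- ifelse(is.na(out$aa_pos), NA_character_,
                          paste0(out$aa_ref, out$aa_pos, out$aa_alt))
  out
}

# intronic dinucleotides flanking internal exon edges of each transcript
splice_sites <- function(exons, transcripts) {
  if (!length(exons)) return(GenomicRanges::GRanges())
  tx_id <- S4Vectors::mcols(exons)$transcript_id
  parts <- S4Vectors::split(exons, tx_id)
  sites <- list()
  for (nm in names(parts)) {
    ex <- IRanges::reduce(IRanges::ranges(parts[[nm]]))
    chr <- as.character(GenomeInfoDb::seqnames(parts[[nm]])[1])
    if (length(ex) < 2) next
    s <- IRanges::start(ex); e <- IRanges::end(ex)
    # donor/acceptor: 2 bases past each internal boundary
    left <- IRanges::IRanges(e[-length(e)] + 1, e[-length(e)] + 2)
    right <- IRanges::IRanges(s[-1] - 2, s[-1] - 1)
    sites[[nm]] <- GenomicRanges::GRanges(chr, c(left, right))
  }
  if (!length(sites)) return(GenomicRanges::GRanges())
  # transcripts live on different chromosomes; merging their seqlevels is
  # intended, so silence the disjoint-seqinfo note
  suppressWarnings(do.call(c, unname(sites)))
}

# effect of a single-base substitution inside a CDS
coding_effect <- function(chrom, pos, ref, alt, cds_gr, cds_seq) {
  none <- list(transcript = NA_character_, effect = "unknown",
               aa_ref = NA_character_, aa_pos = NA_integer_,
               aa_alt = NA_character_)
  locus <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  ov <- GenomicRanges::findOverlaps(locus, cds_gr, ignore.strand = TRUE)
  if (!length(ov)) return(none)
  tx_ids <- S4Vectors::mcols(cds_gr)$transcript_id[S4Vectors::subjectHits(ov)]
  tx_ids <- sort(unique(tx_ids))
  tx <- tx_ids[tx_ids %in% names(cds_seq)][1]
  if (is.na(tx)) return(none)

  seg <- cds_gr[S4Vectors::mcols(cds_gr)$transcript_id == tx]
  strand <- as.character(BiocGenerics::strand(seg))[1]
  o <- order(IRanges::start(IRanges::ranges(seg)),
             decreasing = (strand == "-"))
  seg <- seg[o]
  starts <- IRanges::start(IRanges::ranges(seg))
  ends <- IRanges::end(IRanges::ranges(seg))
  widths <- ends - starts + 1
  offset <- cumsum(c(0, widths[-length(widths)]))
  k <- which(pos >= starts & pos <= ends)[1]
  if (is.na(k)) return(none)
  cds_pos <- if (strand == "+") offset[k] + (pos - starts[k]) + 1
             else offset[k] + (ends[k] - pos) + 1

  seqs <- as.character(cds_seq[[tx]])
  if (nchar(seqs) %% 3 != 0) {
    warning("CDS length of ", tx, " is not a multiple of 3; truncating")
    seqs <- substr(seqs, 1, 3 * (nchar(seqs) %/% 3))
  }
  if (cds_pos > nchar(seqs)) return(none)
  codon_idx <- (cds_pos - 1) %/% 3 + 1
  within <- (cds_pos - 1) %% 3 + 1
  codon <- substr(seqs, 3 * (codon_idx - 1) + 1, 3 * codon_idx)

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref_cds <- if (strand == "+") ref else unname(comp[ref])
  alt_cds <- if (strand == "+") alt else unname(comp[alt])
  if (substr(codon, within, within) != ref_cds) {
    warning("reference base mismatch at ", chrom, ":", pos, " in ", tx,
            " (CDS has ", substr(codon, within, within), ", VCF says ",
            ref_cds, ")")
    return(list(transcript = tx, effect = "unknown",
                aa_ref = NA_character_, aa_pos = NA_integer_,
                aa_alt = NA_character_))
  }
  mut_codon <- codon
  substr(mut_codon, within, within) <- alt_cds
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[codon])
  aa_alt <- unname(code[mut_codon])
  effect <- if (aa_ref == aa_alt) "synonymous"
            else if (aa_alt == "*") "stopgain"
            else if (aa_ref == "*") "other"
            else "nonsynonymous"
  list(transcript = tx, effect = effect, aa_ref = aa_ref,
       aa_pos = codon_idx, aa_alt = aa_alt)
}
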