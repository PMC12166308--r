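#' Generate a synthetic spatial tumor section
#'
#' Builds an m x m spot lattice with a disk-shaped tumor core, an annular
#' margin and normal background, per-spot mRNA UMI depth varying over
#' roughly an order of magnitude (log-normal), and four families of
#' planted SNVs:
#'
#' * group SNVs: `n_groups` sets of windows (one SNV per 100-kb window)
#'   whose counts follow a shared smooth Gaussian spatial field, one field
#'   per group -- the ground truth for SNV-group recovery;
#' * margin SNVs: counts in margin spots with Poisson rate proportional
#'   to `distance^beta` from the tumor boundary (and to spot depth), so
#'   the UMI-normalized burden decays as a power law;
#' * differential SNVs: present essentially only in tumor spots;
#' * noise SNVs: sporadic low counts that must fail the effective-SNV
#'   filter.
#'
#' A per-read evidence table is synthesized from the counts with a
#' controllable duplicate-read rate (exercising UMI deduplication) and a
#' matching somatic VCF is produced that also contains records carrying
#' disqualifying FILTER tags. The `truth` manifest records every planted
#' structure. Generation is deterministic given `seed`.
#'
#' @param m lattice side (default 50, i.e. 2500 spots).
#' @param n_groups number of planted SNV groups (default 4).
#' @param windows_per_group windows (= SNVs) per group (default 25).
#' @param n_margin_snvs margin-decay SNVs (default 60).
#' @param n_diff_snvs tumor-restricted differential SNVs (default 6).
#' @param n_noise_snvs sporadic noise SNVs (default 60).
#' @param beta planted decay exponent of margin burden vs distance
#'   (default -0.8).
#' @param dup_rate probability that a unique read gains a PCR duplicate
#'   row in the evidence table (default 0.3).
#' @param umi_mu,umi_sigma log-normal parameters of per-spot UMI depth
#'   (defaults log(3000) and 0.5).
#' @param seed RNG seed.
#' @return list of class `synthetic_section` with `spots`, `snvs`,
#'   `counts` (true spot x SNV unique-read counts), `evidence`, `vcf`
#'   (call table including filtered-out records) and `truth` (manifest).
#' @export
generate_section <- function(m = 50, n_groups = 4, windows_per_group = 25,
                             n_margin_snvs = 60, n_diff_snvs = 6,
                             n_noise_snvs = 60, beta = -0.8,
                             dup_rate = 0.3, umi_mu = log(3000),
                             umi_sigma = 0.5, seed = 1L) {
  set.seed(seed)
  grid <- expand.grid(x = 0:(m - 1), y = 0:(m - 1))
  n <- nrow(grid)
  ctr <- (m - 1) / 2
  rad <- sqrt((grid$x - ctr)^2 + (grid$y - ctr)^2)
  r_tumor <- 0.22 * m
  r_margin <- 0.40 * m
  region <- ifelse(rad <= r_tumor, "tumor",
                   ifelse(rad <= r_margin, "margin", "normal"))
  depth_scale <- c(tumor = 1.3, margin = 1.0, normal = 0.8)
  umi <- pmax(100L, as.integer(round(
    rlnorm(n, umi_mu, umi_sigma) * depth_scale[region])))
  spots <- data.frame(
    barcode = sprintf("s_%d_%d", grid$x, grid$y),
    x = grid$x, y = grid$y, total_umi = umi, region = region,
    stringsAsFactors = FALSE)

  bases <- c("A", "C", "G", "T")
  rand_snv <- function(k, chrom, pos) {
    ref <- sample(bases, k, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
               filter = "PASS", stringsAsFactors = FALSE)
  }

  counts_i <- integer(0); counts_j <- integer(0); counts_x <- numeric(0)
  snv_list <- list()
  jofs <- 0L

  # --- planted group SNVs: one per 100-kb window, Gaussian spatial field.
  # Fields sit in the four corners, outside the margin annulus, so the
  # group structure and the margin decay stay separately recoverable.
  centers <- rbind(c(0, 0), c(m - 1, 0), c(0, m - 1), c(m - 1, m - 1))
  sigma_f <- m / 14
  group_assign <- integer(0); group_labels <- character(0)
  for (g in seq_len(n_groups)) {
    cg <- centers[(g - 1) %% nrow(centers) + 1, ]
    field <- exp(-((grid$x - cg[1])^2 + (grid$y - cg[2])^2) / (2 * sigma_f^2))
    idx <- 1000L + seq_len(windows_per_group)
    pos <- idx * 100000L + 500L
    sv <- rand_snv(windows_per_group, paste0("chr", g), pos)
    for (w in seq_len(windows_per_group)) {
      cnt <- rpois(n, 3 * field)
      nzi <- which(cnt > 0)
      counts_i <- c(counts_i, nzi)
      counts_j <- c(counts_j, rep(jofs + w, length(nzi)))
      counts_x <- c(counts_x, cnt[nzi])
    }
    snv_list[[length(snv_list) + 1L]] <- sv
    group_assign <- c(group_assign, rep(g - 1L, windows_per_group))
    group_labels <- c(group_labels, paste0("chr", g, "@", idx))
    jofs <- jofs + windows_per_group
  }

  # --- margin-decay SNVs on their own chromosome. The planted power law
  # uses the same distance the margin analysis measures: mean Euclidean
  # distance from each margin spot to its 5 nearest tumor spots.
  is_margin <- region == "margin"
  Dmt <- cross_dist(cbind(grid$x, grid$y)[is_margin, , drop = FALSE],
                    cbind(grid$x, grid$y)[region == "tumor", , drop = FALSE])
  d_margin <- numeric(n)
  d_margin[is_margin] <- apply(Dmt, 1, function(r) mean(sort(r)[1:5]))
  d0 <- median(d_margin[is_margin])
  margin_sv <- rand_snv(n_margin_snvs, "chr9",
                        (2000L + seq_len(n_margin_snvs)) * 100000L + 500L)
  mean_u <- mean(umi)
  for (w in seq_len(n_margin_snvs)) {
    lam <- numeric(n)
    lam[is_margin] <- 0.12 * (d_margin[is_margin] / d0)^beta *
      (umi[is_margin] / mean_u)
    cnt <- rpois(n, lam)
    nzi <- which(cnt > 0)
    counts_i <- c(counts_i, nzi)
    counts_j <- c(counts_j, rep(jofs + w, length(nzi)))
    counts_x <- c(counts_x, cnt[nzi])
  }
  snv_list[[length(snv_list) + 1L]] <- margin_sv
  jofs <- jofs + n_margin_snvs

  # --- tumor-restricted differential SNVs
  diff_sv <- rand_snv(n_diff_snvs, "chr11",
                      (3000L + seq_len(n_diff_snvs)) * 100000L + 500L)
  in_tumor <- region == "tumor"
  for (w in seq_len(n_diff_snvs)) {
    lam <- ifelse(in_tumor, 0.5, 0)
    cnt <- rpois(n, lam)
    nzi <- which(cnt > 0)
    counts_i <- c(counts_i, nzi)
    counts_j <- c(counts_j, rep(jofs + w, length(nzi)))
    counts_x <- c(counts_x, cnt[nzi])
  }
  snv_list[[length(snv_list) + 1L]] <- diff_sv
  jofs <- jofs + n_diff_snvs

  # --- sporadic noise SNVs (must fail the effective filter)
  noise_sv <- rand_snv(n_noise_snvs, "chr10",
                       (4000L + seq_len(n_noise_snvs)) * 100000L + 500L)
  for (w in seq_len(n_noise_snvs)) {
    k <- sample(1:3, 1)
    nzi <- sample.int(n, k)
    counts_i <- c(counts_i, nzi)
    counts_j <- c(counts_j, rep(jofs + w, length(nzi)))
    counts_x <- c(counts_x, sample(1:2, k, replace = TRUE))
  }
  snv_list[[length(snv_list) + 1L]] <- noise_sv
  jofs <- jofs + n_noise_snvs

  snvs <- do.call(rbind, snv_list)
  snvs$snv_id <- snv_id(snvs)
  counts <- sparseMatrix(i = counts_i, j = counts_j, x = counts_x,
                         dims = c(n, nrow(snvs)),
                         dimnames = list(spots$barcode, snvs$snv_id))

  evidence <- counts_to_evidence(counts, spots, snvs, dup_rate = dup_rate)

  # VCF: all planted SNVs PASS, plus records that must be filtered out
  filtered_recs <- data.frame(
    chrom = "chr12",
    pos = c(1000L, 2000L, 3000L),
    ref = c("A", "C", "G"), alt = c("G", "T", "A"),
    filter = c("germline", "weak_evidence;strand_bias", "panel_of_normals"),
    stringsAsFactors = FALSE)
  vcf_tab <- rbind(snvs[, c("chrom", "pos", "ref", "alt", "filter")],
                   filtered_recs)

  reads <- Matrix::colSums(counts)
  nspots <- Matrix::colSums(counts > 0)
  truth <- list(
    seed = seed, m = m, beta = beta,
    r_tumor = r_tumor, r_margin = r_margin,
    group_assignment = setNames(group_assign, group_labels),
    margin_snv_ids = snv_id(margin_sv),
    diff_snv_ids = snv_id(diff_sv),
    noise_snv_ids = snv_id(noise_sv),
    effective_ids = snvs$snv_id[reads >= 20 & nspots >= 5],
    filtered_vcf_records = nrow(filtered_recs),
    dup_rate = dup_rate)
  structure(list(spots = spots, snvs = snvs, counts = counts,
                 evidence = evidence, vcf = vcf_tab, truth = truth),
            class = "synthetic_section")
}

# expand a count matrix into per-read evidence rows with duplicates and
# some reference-allele reads
counts_to_evidence <- function(counts, spots, snvs, dup_rate = 0.3) {
  tm <- as(counts, "TsparseMatrix")
  o <- order(tm@j, tm@i)
  ei <- tm@i[o] + 1L; ej <- tm@j[o] + 1L; ex <- tm@x[o]
  reps <- as.integer(ex)
  bc <- rep(spots$barcode[ei], reps)
  jj <- rep(ej, reps)
  ord <- sequence(reps)
  umi <- sprintf("U%06d%s", rep(seq_along(reps), reps), ord)
  ev <- data.frame(
    read_id = sprintf("r%07d", seq_along(bc)),
    barcode = bc, umi = umi,
    chrom = snvs$chrom[jj], pos = snvs$pos[jj],
    allele = snvs$alt[jj], stringsAsFactors = FALSE)
  # PCR duplicates: same (barcode, umi, locus), new read id
  dup <- ev[runif(nrow(ev)) < dup_rate, , drop = FALSE]
  if (nrow(dup))
    dup$read_id <- sprintf("d%07d", seq_len(nrow(dup)))
  # sprinkle reference-allele reads (must not be counted)
  nref <- max(1L, nrow(ev) %/% 10L)
  ridx <- sample.int(nrow(ev), nref)
  refr <- ev[ridx, , drop = FALSE]
  refr$read_id <- sprintf("f%07d", seq_len(nref))
  refr$umi <- paste0(refr$umi, "R")
  refr$allele <- snvs$ref[match(paste(refr$chrom, refr$pos),
                                paste(snvs$chrom, snvs$pos))]
  out <- rbind(ev, dup, refr)
  rownames(out) <- NULL
  out
}

#' Write a synthetic section to disk
#'
#' Emits exactly the formats the readers consume: `spots.tsv`,
#' `evidence.tsv`, `calls.vcf` and `manifest.json` (the ground-truth
#' manifest).
#'
#' @param section `synthetic_section` from [generate_section()].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_section <- function(section, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_spot_table(section$spots, file.path(dir, "spots.tsv"))
  write_evidence(section$evidence, file.path(dir, "evidence.tsv"))
  write_vcf(section$vcf, file.path(dir, "calls.vcf"))
  truth <- section$truth
  # keep window -> group names through JSON (named vectors lose names)
  truth$group_assignment <- as.list(truth$group_assignment)
  jsonlite::write_json(truth, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_section
#' @export
read_manifest <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  man$group_assignment <- unlist(man$group_assignment)
  man
}

#' Generate a toy genome with annotation, CDS and planted variants
#'
#' Builds a small two-chromosome genome of multi-exon protein-coding
#' genes on both strands (each: 30-bp 5'UTR, a 150-bp and a 300-bp CDS
#' exon separated by a 200-bp intron, 30-bp 3'UTR) plus one noncoding
#' gene, together with a GTF, spliced CDS FASTA and a planted variant
#' table covering every annotation class: nonsynonymous (G12D-style codon
#' 12 and an L40P-style codon 40 change whose full 31-aa context exists),
#' synonymous third-position, 5'/3' UTR, intronic, splice-site,
#' intergenic, noncoding-exon and a minus-strand nonsynonymous change.
#' Expected region/effect/amino-acid annotations are computed from the
#' construction itself and stored with each variant.
#'
#' @param n_genes number of protein-coding genes (default 9; one
#'   noncoding gene is always added).
#' @param seed RNG seed.
#' @return list of class `toy_genome` with `genome` (named chrom ->
#'   sequence), `gtf` (data.frame of GTF fields), `cds` (named transcript
#'   -> CDS sequence), `proteins`, `variants` (planted variant table with
#'   expectations) and `gene_lengths`.
#' @export
generate_toy_genome <- function(n_genes = 9, seed = 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  revcomp <- function(s) paste(rev(unname(comp[strsplit(s, "")[[1]]])),
                               collapse = "")
  rand_seq <- function(k) paste(sample(bases, k, replace = TRUE),
                                collapse = "")

  utr5_len <- 30L; utr3_len <- 30L; intron_len <- 200L
  n_codons <- 150L
  exon1_cds <- 150L   # codons 1..50
  gene_span <- utr5_len + exon1_cds + intron_len +
    (3L * n_codons - exon1_cds) + utr3_len

  chrom_seq <- list(chrA = character(0), chrB = character(0))
  cursor <- c(chrA = 1L, chrB = 1L)
  gap <- 500L
  gtf <- list(); cds <- list(); proteins <- list()
  gene_meta <- list()

  push_seq <- function(chrom, s) {
    chrom_seq[[chrom]] <<- c(chrom_seq[[chrom]], s)
    cursor[chrom] <<- cursor[chrom] + nchar(s)
  }
  gtf_row <- function(chrom, feat, a, b, strand, gid, tid, biotype) {
    attr <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s"; gene_biotype "%s";',
                    gid, tid, gid, biotype)
    data.frame(seqname = chrom, source = "toy", feature = feat,
               start = a, end = b, score = ".", strand = strand,
               frame = ".", attribute = attr, stringsAsFactors = FALSE)
  }

  for (i in seq_len(n_genes)) {
    chrom <- if (i <= ceiling(n_genes / 2)) "chrA" else "chrB"
    strand <- if (i %% 2 == 1) "+" else "-"
    gid <- paste0("G", i); tid <- paste0("TX", i)

    codons <- sample(sense, n_codons, replace = TRUE)
    codons[1] <- "ATG"
    codons[n_codons] <- "TAA"
    codons[12] <- "GGT"  # glycine: G12D-style target
    codons[40] <- "CTG"  # leucine: L40P-style target
    codons[80] <- "GGT"  # third-position synonymous target
    cds_seq <- paste(codons, collapse = "")
    utr5 <- rand_seq(utr5_len); utr3 <- rand_seq(utr3_len)
    intron <- rand_seq(intron_len)
    substr(intron, 1, 2) <- "GT"; substr(intron, intron_len - 1, intron_len) <- "AG"
    tx_seq <- paste0(utr5, substr(cds_seq, 1, exon1_cds), intron,
                     substr(cds_seq, exon1_cds + 1, 3 * n_codons), utr3)
    stopifnot(nchar(tx_seq) == gene_span)

    push_seq(chrom, rand_seq(gap))
    s <- unname(cursor[chrom])
    gseq <- if (strand == "+") tx_seq else revcomp(tx_seq)
    push_seq(chrom, gseq)

    # transcript-coordinate intervals -> genomic; factory so each gene's
    # map captures its own start/strand rather than the loop's last values
    make_tx2g <- function(s0, str0, span0) {
      force(s0); force(str0); force(span0)
      function(t) if (str0 == "+") s0 + t - 1L else s0 + span0 - t
    }
    tx2g <- make_tx2g(s, strand, gene_span)
    iv <- function(a, b) if (strand == "+") c(tx2g(a), tx2g(b))
                         else c(tx2g(b), tx2g(a))
    exonA <- iv(1L, utr5_len + exon1_cds)
    exonB <- iv(utr5_len + exon1_cds + intron_len + 1L, gene_span)
    cds1 <- iv(utr5_len + 1L, utr5_len + exon1_cds)
    cds2 <- iv(utr5_len + exon1_cds + intron_len + 1L, gene_span - utr3_len)
    u5 <- iv(1L, utr5_len)
    u3 <- iv(gene_span - utr3_len + 1L, gene_span)
    whole <- iv(1L, gene_span)

    gtf[[length(gtf) + 1L]] <- rbind(
      gtf_row(chrom, "gene", whole[1], whole[2], strand, gid, tid, "protein_coding"),
      gtf_row(chrom, "transcript", whole[1], whole[2], strand, gid, tid, "protein_coding"),
      gtf_row(chrom, "exon", exonA[1], exonA[2], strand, gid, tid, "protein_coding"),
      gtf_row(chrom, "exon", exonB[1], exonB[2], strand, gid, tid, "protein_coding"),
      gtf_row(chrom, "CDS", cds1[1], cds1[2], strand, gid, tid, "protein_coding"),
      gtf_row(chrom, "CDS", cds2[1], cds2[2], strand, gid, tid, "protein_coding"),
      gtf_row(chrom, "five_prime_utr", u5[1], u5[2], strand, gid, tid, "protein_coding"),
      gtf_row(chrom, "three_prime_utr", u3[1], u3[2], strand, gid, tid, "protein_coding"))
    cds[[tid]] <- cds_seq
    prot <- as.character(Biostrings::translate(Biostrings::DNAString(cds_seq)))
    proteins[[tid]] <- sub("\\*$", "", prot)
    gene_meta[[gid]] <- list(gid = gid, tid = tid, chrom = chrom,
                             strand = strand, start = s,
                             span = gene_span, codons = codons,
                             tx2g = tx2g)
  }

  # one noncoding gene on chrB
  push_seq("chrB", rand_seq(gap))
  s_nc <- cursor["chrB"]
  nc_len <- 400L
  push_seq("chrB", rand_seq(nc_len))
  gtf[[length(gtf) + 1L]] <- rbind(
    gtf_row("chrB", "gene", s_nc, s_nc + nc_len - 1L, "+", "GNC", "TXNC", "lincRNA"),
    gtf_row("chrB", "transcript", s_nc, s_nc + nc_len - 1L, "+", "GNC", "TXNC", "lincRNA"),
    gtf_row("chrB", "exon", s_nc, s_nc + nc_len - 1L, "+", "GNC", "TXNC", "lincRNA"))
  push_seq("chrA", rand_seq(gap))
  push_seq("chrB", rand_seq(gap))

  genome <- vapply(chrom_seq, paste, character(1), collapse = "")
  gtf <- do.call(rbind, gtf)

  # --- planted variants with construction-derived expectations
  cds_to_tx <- function(c) ifelse(c <= exon1_cds, utr5_len + c,
                                  utr5_len + intron_len + c)
  tx_base <- function(meta, t) {
    g <- meta$tx2g(t)
    b <- substr(genome[[meta$chrom]], g, g)
    if (meta$strand == "+") b else unname(comp[b])
  }
  plant <- function(meta, t, alt_tx, region, effect, aa_change) {
    g <- meta$tx2g(t)
    ref_tx <- tx_base(meta, t)
    ref_g <- substr(genome[[meta$chrom]], g, g)
    alt_g <- if (meta$strand == "+") alt_tx else unname(comp[alt_tx])
    stopifnot(ref_tx != alt_tx)
    data.frame(chrom = meta$chrom, pos = g, ref = ref_g, alt = alt_g,
               filter = "PASS", gene = meta$gid,
               expected_region = region, expected_effect = effect,
               expected_aa_change = aa_change, stringsAsFactors = FALSE)
  }
  g1 <- gene_meta[["G1"]]   # plus strand
  g2 <- gene_meta[["G2"]]   # minus strand
  aa_of <- function(codon) unname(code[codon])
  v <- list(
    plant(g1, cds_to_tx(35L), "A", "exonic", "nonsynonymous", "G12D"),
    plant(g1, cds_to_tx(119L), "C", "exonic", "nonsynonymous", "L40P"),
    plant(g1, cds_to_tx(240L), "C", "exonic", "synonymous", "G80G"),
    plant(g1, 10L, flip_base(tx_base(g1, 10L)), "UTR5", NA, NA),
    plant(g1, gene_span - 10L, flip_base(tx_base(g1, gene_span - 10L)), "UTR3", NA, NA),
    plant(g1, utr5_len + exon1_cds + 50L,
          flip_base(tx_base(g1, utr5_len + exon1_cds + 50L)), "intronic", NA, NA),
    plant(g1, utr5_len + exon1_cds + 1L, "A", "splicing", NA, NA),
    plant(g2, cds_to_tx(35L), "A", "exonic", "nonsynonymous", "G12D")
  )
  v <- do.call(rbind, v)
  # intergenic: inside the first gap of chrA
  ig_pos <- 50L
  v <- rbind(v, data.frame(
    chrom = "chrA", pos = ig_pos,
    ref = substr(genome[["chrA"]], ig_pos, ig_pos),
    alt = flip_base(substr(genome[["chrA"]], ig_pos, ig_pos)),
    filter = "PASS", gene = NA_character_,
    expected_region = "intergenic", expected_effect = NA,
    expected_aa_change = NA, stringsAsFactors = FALSE))
  # noncoding exon variant
  nc_pos <- s_nc + 100L
  v <- rbind(v, data.frame(
    chrom = "chrB", pos = nc_pos,
    ref = substr(genome[["chrB"]], nc_pos, nc_pos),
    alt = flip_base(substr(genome[["chrB"]], nc_pos, nc_pos)),
    filter = "PASS", gene = "GNC",
    expected_region = "ncRNA", expected_effect = NA,
    expected_aa_change = NA, stringsAsFactors = FALSE))
  v$snv_id <- snv_id(v)

  gl <- setNames(rep(gene_span, n_genes), paste0("G", seq_len(n_genes)))
  gl["GNC"] <- nc_len
  structure(list(genome = genome, gtf = gtf,
                 cds = vapply(cds, identity, character(1)),
                 proteins = vapply(proteins, identity, character(1)),
                 variants = v, gene_lengths = gl,
                 n_codons = n_codons, protein_length = n_codons - 1L),
            class = "toy_genome")
}

# deterministic single-base change used for non-coding planted variants
flip_base <- function(b) c(A = "C", C = "A", G = "T", T = "G")[[b]]

#' Write a toy genome bundle to disk
#'
#' Emits `genome.fa`, `genes.gtf`, `cds.fa` and `variants.tsv` under
#' `dir`.
#'
#' @param tg `toy_genome` from [generate_toy_genome()].
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_toy_genome <- function(tg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(tg$genome, file.path(dir, "genome.fa"))
  gt <- tg$gtf
  writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
                     gt$seqname, gt$source, gt$feature, gt$start, gt$end,
                     gt$score, gt$strand, gt$frame, gt$attribute),
             file.path(dir, "genes.gtf"))
  write_fasta(tg$cds, file.path(dir, "cds.fa"))
  fwrite(tg$variants, file.path(dir, "variants.tsv"), sep = "\t")
  invisible(dir)
}

# minimal FASTA writer for named character vectors
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
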