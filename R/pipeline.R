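#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Defaults
#' follow the method's standard settings: effective-SNV thresholds of 20
#' unique reads and 5 spots, 100-kb windows, Gaussian k-NN smoothing with
#' bandwidth equal to the mean k-NN distance, top-50% spot/partner
#' selection, Leiden resolution 5, k = 5 nearest tumor spots for margin
#' distances, and 8-15-mer peptides. `bin_size = 1` leaves spots
#' unaggregated; set 100 for raw Stereo-seq lattices (bin100).
#'
#' @param ... overrides of the defaults, by name.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_unique_reads = 20L,
    min_spots = 5L,
    bin_size = 1L,
    window_size = 100000L,
    knn_k = 6L,
    alpha = NA_real_,          # NA: mean k-NN distance of the section
    top_fraction = 0.5,
    decay_alpha = 0.5,
    leiden_resolution = 5.0,
    distance_k = 5L,
    lfc_min = 1.0,
    p_max = 0.5,
    kmin = 8L,
    kmax = 15L,
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$min_unique_reads >= 1, cfg$min_spots >= 1,
            cfg$bin_size >= 1, cfg$window_size >= 1, cfg$knn_k >= 1,
            cfg$top_fraction > 0, cfg$top_fraction <= 1,
            cfg$decay_alpha > 0, cfg$leiden_resolution > 0,
            cfg$distance_k >= 1, cfg$kmin >= 1, cfg$kmax >= cfg$kmin)
  if (!is.na(cfg$alpha) && cfg$alpha <= 0) stop("alpha must be positive")
  invisible(cfg)
}

#' Read / write a key-value config file
#'
#' Plain `key = value` text; unknown keys are rejected, missing keys take
#' the defaults of [pipeline_config()].
#'
#' @param path config file.
#' @return `pipeline_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- lapply(kv, function(p) {
    v <- p[2]
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  do.call(pipeline_config, setNames(vals, keys))
}

#' @rdname read_config
#' @param cfg `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, format, character(1))), path)
  invisible(path)
}

#' Run the full pipeline on a section directory
#'
#' Consumes `spots.tsv`, `evidence.tsv` and `calls.vcf` under
#' `input_dir` (the layout written by [write_section()]), runs matrix
#' construction, effective-SNV filtering, binarization, UMI
#' normalization, window aggregation, spatial smoothing, SNV-group
#' detection, Moran's I, and -- when region labels are present -- the
#' margin distance-decay fit and region-differential SNVs. When a
#' `genome/` subdirectory with `genes.gtf`, `cds.fa` and `variants.tsv`
#' is present, the neoantigen stage is run on those variants as well.
#' All stages log counts in/out; outputs are written as TSV (plus an MTX
#' bundle of the effective counts) under `out_dir`, together with the
#' config used.
#'
#' @param input_dir section directory.
#' @param out_dir output directory (created).
#' @param config `pipeline_config`.
#' @return invisibly, a list with every intermediate result.
#' @export
run_pipeline <- function(input_dir, out_dir, config = pipeline_config()) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spots <- read_spot_table(file.path(input_dir, "spots.tsv"))
  evidence <- read_evidence(file.path(input_dir, "evidence.tsv"))
  snvs <- read_filtered_vcf(file.path(input_dir, "calls.vcf"))
  message(nrow(snvs), " SNVs retained from VCF")

  raw <- build_spot_snv_matrix(evidence, snvs, spots)
  if (config$bin_size > 1) raw <- aggregate_spot_bins(raw, config$bin_size)
  eff <- filter_effective(raw, config$min_unique_reads, config$min_spots)
  message(ncol(eff$counts), " of ", ncol(raw$counts), " SNVs effective")

  bin <- binarize(eff)
  norm <- normalize_snv(bin)
  burden <- spot_burden(bin)

  alpha <- if (is.na(config$alpha)) NULL else config$alpha
  w <- spatial_weights(eff$spots, k = config$knn_k, alpha = alpha)
  wm <- window_aggregate(eff, config$window_size)
  wm <- smooth_windows(wm, w)
  corr <- window_correlation(wm, config$top_fraction)
  graph <- build_group_graph(corr, config$top_fraction, config$decay_alpha)
  grp <- leiden_groups(graph, resolution = config$leiden_resolution,
                       seed = config$seed)
  scores <- group_scores(wm, grp$assignment)
  message(length(unique(grp$assignment)), " SNV groups over ",
          ncol(wm$counts), " windows")

  moran_groups <- morans_i_columns(scores, w)
  win_norm <- log1p(Diagonal(x = 1 / eff$spots$total_umi) %*% wm$counts)
  moran_windows <- morans_i_columns(as.matrix(win_norm), w)
  moran_windows$feature <- colnames(wm$counts)

  fit <- NULL; dist_tab <- NULL; diff_tab <- NULL
  if (any(eff$spots$region == "tumor") && any(eff$spots$region == "margin")) {
    dist_tab <- distance_to_tumor(eff$spots, k = config$distance_k)
    mb <- burden[match(dist_tab$barcode, names(burden))]
    fit <- burden_distance_fit(mb, dist_tab$distance)
    labs <- eff$spots$region
    if (length(unique(labs[labs != "unassigned"])) >= 2)
      diff_tab <- differential_snvs(norm, labs, lfc_min = config$lfc_min,
                                    p_max = config$p_max)
  }

  neo <- NULL
  gdir <- file.path(input_dir, "genome")
  if (file.exists(file.path(gdir, "genes.gtf")))
    neo <- run_neoantigen_stage(gdir, out_dir, config)

  # ---- outputs
  fwrite(eff$snvs, file.path(out_dir, "effective_snvs.tsv"), sep = "\t")
  write_expression_matrix(eff$counts, file.path(out_dir, "effective_counts"))
  fwrite(data.frame(barcode = names(burden), burden = burden),
         file.path(out_dir, "spot_burden.tsv"), sep = "\t")
  fwrite(data.frame(window = names(grp$assignment),
                    group = as.integer(grp$assignment)),
         file.path(out_dir, "window_groups.tsv"), sep = "\t")
  fwrite(cbind(data.frame(barcode = rownames(scores)), as.data.frame(scores)),
         file.path(out_dir, "group_scores.tsv"), sep = "\t")
  el <- igraph::as_data_frame(graph, what = "edges")
  names(el)[1:2] <- c("source", "target")
  fwrite(el, file.path(out_dir, "graph_edges.tsv"), sep = "\t")
  fwrite(moran_groups, file.path(out_dir, "moran_groups.tsv"), sep = "\t")
  fwrite(moran_windows, file.path(out_dir, "moran_windows.tsv"), sep = "\t")
  if (!is.null(fit))
    fwrite(as.data.frame(fit[c("slope", "intercept", "r_squared", "n",
                               "n_dropped")]),
           file.path(out_dir, "margin_fit.tsv"), sep = "\t")
  if (!is.null(dist_tab))
    fwrite(dist_tab, file.path(out_dir, "margin_distance.tsv"), sep = "\t")
  if (!is.null(diff_tab))
    fwrite(diff_tab, file.path(out_dir, "differential_snvs.tsv"), sep = "\t")
  write_config(config, file.path(out_dir, "config.txt"))

  invisible(list(spots = eff$spots, raw = raw, effective = eff,
                 normalized = norm, burden = burden, weights = w,
                 windows = wm, corr = corr, graph = graph, groups = grp,
                 scores = scores, moran_groups = moran_groups,
                 moran_windows = moran_windows, margin_fit = fit,
                 margin_distance = dist_tab, differential = diff_tab,
                 neoantigen = neo, config = config))
}

# annotate the genome-bundle variants, build mutant peptides, filter them
# against the bundle's own proteome, and export
run_neoantigen_stage <- function(gdir, out_dir, config) {
  vars <- as.data.frame(fread(file.path(gdir, "variants.tsv"), sep = "\t"))
  vcf_path <- file.path(gdir, "variants.vcf")
  write_vcf(vars, vcf_path)
  calls <- read_filtered_vcf(vcf_path)
  ann <- annotate_snvs(calls, file.path(gdir, "genes.gtf"),
                       file.path(gdir, "cds.fa"))
  cds_seq <- Biostrings::readDNAStringSet(file.path(gdir, "cds.fa"))
  nonsyn <- ann[!is.na(ann$effect) & ann$effect == "nonsynonymous", ,
                drop = FALSE]
  message(nrow(nonsyn), " nonsynonymous variants enter the peptide stage")
  peps <- list()
  for (i in seq_len(nrow(nonsyn))) {
    ctx <- extract_context(nonsyn[i, ], cds_seq)
    peps[[i]] <- enumerate_peptides(ctx, config$kmin, config$kmax)
  }
  peps <- do.call(rbind, peps)
  if (is.null(peps))
    peps <- enumerate_peptides(list(mut_context = "", center_index = 0,
                                    gene = NA, snv_id = NA, aa_change = NA))
  lig <- file.path(gdir, "healthy_ligands.txt")
  idx <- build_exclusion_index(cds_seq,
                               if (file.exists(lig)) lig else character(0),
                               config$kmin, config$kmax)
  known <- file.path(gdir, "known_epitopes.txt")
  cand <- filter_candidates(peps, idx,
                            if (file.exists(known)) known else character(0))
  message(nrow(cand), " of ", nrow(peps),
          " mutant peptides survive normal-peptide exclusion")
  export_for_hla_tools(cand, file.path(out_dir, "neoantigen_peptides.fa"),
                       file.path(out_dir, "neoantigen_candidates.tsv"))
  cand
}

#' Check pipeline results against a synthetic-section manifest
#'
#' The master integration check: recomputes every planted ground truth of
#' [generate_section()] from the pipeline outputs and compares.
#'
#' * `effective_match` -- the recovered effective-SNV set equals the
#'   manifest's brute-force expectation;
#' * `group_ari` / `group_recovery` -- adjusted Rand index between
#'   planted and recovered window groups (restricted to planted windows)
#'   with the 0.8 pass line;
#' * `slope`, `slope_ok` -- margin decay slope within 0.2 of the planted
#'   exponent (binarization and zero-truncation compress the realized
#'   decay, see the methods vignette);
#' * `diff_recovered` -- planted tumor-restricted SNVs called
#'   tumor-differential.
#'
#' @param res result list of [run_pipeline()].
#' @param manifest `truth` element of a section (or [read_manifest()]).
#' @return list of named checks; `all_ok` aggregates the booleans.
#' @export
check_manifest <- function(res, manifest) {
  eff_ids <- res$effective$snvs$snv_id
  effective_match <- setequal(eff_ids, manifest$effective_ids)

  truth <- manifest$group_assignment
  common <- intersect(names(truth), names(res$groups$assignment))
  ari <- mclust::adjustedRandIndex(truth[common],
                                   res$groups$assignment[common])
  slope <- if (is.null(res$margin_fit)) NA_real_ else res$margin_fit$slope
  slope_ok <- !is.na(slope) && abs(slope - manifest$beta) <= 0.2
  diff_ok <- TRUE
  if (!is.null(res$differential)) {
    tum <- res$differential[res$differential$group == "tumor", ]
    diff_ok <- all(manifest$diff_snv_ids %in% tum$snv_id)
  }
  out <- list(effective_match = effective_match,
              group_ari = ari, group_recovery = ari >= 0.8,
              slope = slope, slope_ok = slope_ok,
              diff_recovered = diff_ok)
  out$all_ok <- effective_match && out$group_recovery && slope_ok && diff_ok
  out
}
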