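#' Gene mutation frequency
#'
#' Counts the distinct effective SNV loci annotated to each gene and
#' normalizes by gene length, giving a per-gene mutational pressure. The
#' mean occurrence is the average number of spots carrying each of the
#' gene's SNVs.
#'
#' @param x `spot_snv_matrix` of effective SNVs; its SNV table must carry a
#'   `gene` column (see [annotate_snvs()]).
#' @param gene_lengths named numeric vector, gene -> length in bp.
#' @return data.frame with columns `gene`, `n_effective_sites`,
#'   `gene_length`, `frequency` and `mean_occurrence`, sorted by decreasing
#'   frequency. Genes with no SNVs are absent.
#' @export
gene_mutation_frequency <- function(x, gene_lengths) {
  stopifnot(is(x, "spot_snv_matrix"))
  snvs <- x$snvs
  if (is.null(snvs$gene)) stop("SNV table has no 'gene' column; annotate first")
  occ <- Matrix::colSums(x$counts > 0)
  keep <- !is.na(snvs$gene)
  genes <- snvs$gene[keep]
  occ <- occ[keep]
  loci <- paste(snvs$chrom, snvs$pos)[keep]
  if (!length(genes)) {
    return(data.frame(gene = character(), n_effective_sites = integer(),
                      gene_length = numeric(), frequency = numeric(),
                      mean_occurrence = numeric()))
  }
  n_sites <- vapply(split(loci, genes), function(l) length(unique(l)), integer(1))
  mean_occ <- vapply(split(occ, genes), mean, numeric(1))
  g <- names(n_sites)
  len <- gene_lengths[g]
  if (anyNA(len))
    stop("no length supplied for gene(s): ",
         paste(g[is.na(len)], collapse = ", "))
  if (any(len <= 0)) stop("gene lengths must be positive")
  out <- data.frame(gene = g, n_effective_sites = as.integer(n_sites),
                    gene_length = as.numeric(len),
                    frequency = n_sites / len,
                    mean_occurrence = mean_occ,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$frequency, out$gene), , drop = FALSE]
}

#' Differential SNVs between spot groups
#'
#' One-vs-rest Wilcoxon rank-sum test on normalized SNV values per group
#' (e.g. tumor subclones), with a log2 fold change of group means
#' (pseudocount 1e-9) and Benjamini-Hochberg adjusted p values. Rows
#' passing `log_fold_change >= lfc_min` and `p < p_max` are reported.
#' SNVs constant across all spots get `p = 1`, `log_fold_change = 0`.
#'
#' @param x `spot_snv_matrix` with the normalized layer.
#' @param groups character/factor of spot labels, one per spot; at least
#'   two groups with two spots each.
#' @param lfc_min minimum log2 fold change (default 1, mirroring the
#'   convention for subclone-specific SNVs).
#' @param p_max p-value ceiling for reporting. The permissive default of
#'   0.5 keeps weakly supported subclone markers for downstream trajectory
#'   work; 0.05 is the conventional choice for a strict differential call.
#' @return data.frame with columns `snv_id`, `group`, `log_fold_change`,
#'   `p`, `adjusted_p`, sorted by group then p.
#' @export
differential_snvs <- function(x, groups, lfc_min = 1.0, p_max = 0.5) {
  stopifnot(is(x, "spot_snv_matrix"))
  groups <- as.character(groups)
  if (length(groups) != nrow(x$counts))
    stop("groups must have one label per spot")
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 spots each")
  eps <- 1e-9
  m <- x$counts
  res <- list()
  for (g in names(tab)) {
    in_g <- groups == g
    for (j in seq_len(ncol(m))) {
      v <- m[, j]
      a <- v[in_g]; b <- v[!in_g]
      if (max(v) == min(v)) {
        p <- 1; lfc <- 0
      } else {
        p <- suppressWarnings(wilcox.test(a, b)$p.value)
        lfc <- log2((mean(a) + eps) / (mean(b) + eps))
      }
      res[[length(res) + 1L]] <- data.frame(
        snv_id = colnames(m)[j], group = g,
        log_fold_change = lfc, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$adjusted_p <- p.adjust(out$p, method = "BH")
  out <- out[out$log_fold_change >= lfc_min & out$p < p_max, , drop = FALSE]
  out <- out[order(out$group, out$p, out$snv_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
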