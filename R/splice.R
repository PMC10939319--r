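#' Simes combination of per-exon p-values
#'
#' `min_i p_(i) * m / i` over the sorted p-values; an FDR-valid gene-level
#' p-value for "at least one exon departs".
#'
#' @param p Vector of exon p-values.
#' @return Gene-level Simes p-value.
#' @export
simes_p <- function(p) {
  p <- sort(p)
  min(1, min(p * length(p) / seq_along(p)))
}

#' Exon-level differential-splicing test
#'
#' Screens for genes whose treatment response differs between exons. For
#' every exon the paired family + treatment model is fitted to exon
#' log2-CPM with precision weights and empirical-Bayes moderation exactly
#' as in the gene-level analysis; each exon's treatment log2 fold change is
#' then re-expressed as a deviation from the average fold change of the
#' gene's other exons (so a shift common to all exons of a gene cancels),
#' tested with a moderated t, aggregated per gene with Simes' rule, and the
#' gene-level p-values are BH-adjusted. Genes with a single exon cannot
#' show relative exon usage changes and are skipped (and counted).
#'
#' @param exon_counts Data frame with columns `gene_id`, `exon_id`, then
#'   one column per sample of the stratum.
#' @param sheet Matching sample-sheet rows.
#' @param fdr DSG flag threshold on adjusted gene p (default 0.05).
#' @param min_cpm,min_samples Exon-level expression filter.
#' @param prior_count Prior count for log2-CPM.
#' @return A list with `genes` (data frame: gene, n_exons, best_exon,
#'   deviation_logFC, gene_p, adj_p, dsg), `exons` (per-exon deviations,
#'   t and p) and `n_single_exon` (genes skipped).
#' @export
splice_test <- function(exon_counts, sheet, fdr = 0.05,
                        min_cpm = 1, min_samples = NULL, prior_count = 0.5) {
  if (!all(c("gene_id", "exon_id") %in% names(exon_counts))) {
    stop("exon_counts must have gene_id and exon_id columns", call. = FALSE)
  }
  samples <- sheet$sample_id
  if (!all(samples %in% names(exon_counts))) {
    stop("exon table is missing sample columns: ",
         paste(setdiff(samples, names(exon_counts)), collapse = ", "),
         call. = FALSE)
  }
  mat <- as.matrix(exon_counts[, samples, drop = FALSE])
  gene <- exon_counts$gene_id
  exon <- exon_counts$exon_id

  keep <- filter_expressed(mat, min_cpm, min_samples)
  mat <- mat[keep, , drop = FALSE]
  gene <- gene[keep]; exon <- exon[keep]

  multi <- names(which(table(gene) >= 2L))
  n_single <- length(unique(gene)) - length(multi)
  sel <- gene %in% multi
  mat <- mat[sel, , drop = FALSE]
  gene <- gene[sel]; exon <- exon[sel]
  if (nrow(mat) == 0L) {
    return(list(genes = data.frame(gene = character(), n_exons = integer(),
                                   best_exon = character(),
                                   deviation_logFC = numeric(),
                                   gene_p = numeric(), adj_p = numeric(),
                                   dsg = logical()),
                exons = NULL, n_single_exon = n_single))
  }
  rownames(mat) <- paste(gene, exon, sep = ":")

  lc <- cpm(mat, log = TRUE, prior_count = prior_count)
  design <- paired_design(sheet)
  w <- estimate_precision_weights(lc, design)
  fit <- fit_weighted_lm(lc, design, weights = w$weights)
  sq <- squeeze_var(fit$sigma^2, fit$df_residual)
  beta <- fit$coefficients[, "treatmentltherm"]
  se2 <- fit$stdev_unscaled[, "treatmentltherm"]^2 * sq$var_post
  df_total <- fit$df_residual + sq$df_prior

  dev <- numeric(length(beta)); dev_se2 <- dev
  for (g in unique(gene)) {
    idx <- which(gene == g)
    m <- length(idx)
    for (k in seq_along(idx)) {
      others <- idx[-k]
      dev[idx[k]] <- beta[idx[k]] - mean(beta[others])
      dev_se2[idx[k]] <- se2[idx[k]] + sum(se2[others]) / (m - 1)^2
    }
  }
  tstat <- dev / sqrt(dev_se2)
  p_exon <- 2 * stats::pt(-abs(tstat), df = df_total)

  genes_u <- unique(gene)
  gene_rows <- lapply(genes_u, function(g) {
    idx <- which(gene == g)
    best <- idx[which.min(p_exon[idx])]
    data.frame(gene = g, n_exons = length(idx),
               best_exon = as.character(exon[best]),
               deviation_logFC = dev[best],
               gene_p = simes_p(p_exon[idx]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, gene_rows)
  res$adj_p <- bh_adjust(res$gene_p)
  res$dsg <- res$adj_p <= fdr
  exons <- data.frame(gene = gene, exon = exon, logFC = beta,
                      deviation_logFC = dev, t = tstat, p = p_exon,
                      stringsAsFactors = FALSE, row.names = NULL)
  list(genes = res, exons = exons, n_single_exon = n_single)
}
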