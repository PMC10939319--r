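#' Pipeline run configuration
#'
#' Collects all thresholds and paths for [run_pipeline()]. Any input path
#' left `NULL` is filled from the synthetic-data generators (using
#' `sim` and `seed`), so a full run needs no external files.
#'
#' @param out_dir Output directory (created if absent).
#' @param counts,exon_counts,sample_sheet,phenotypes,gene_sets Input file
#'   paths (`NULL` = simulate).
#' @param trait Named IR vector or `NULL` to derive it from the simulated
#'   configuration.
#' @param de_alpha,de_use_adjusted DEG threshold and whether it applies to
#'   BH-adjusted p (default 0.05, adjusted).
#' @param dsg_fdr DSG threshold on adjusted gene p.
#' @param corr_alpha Raw-p threshold for the Corr sign call.
#' @param cld_alpha Letter-display significance level.
#' @param beta,k,partner_edge_floor Network parameters (soft-threshold
#'   power, partner count, partner-partner edge floor).
#' @param min_cpm,min_samples Expression filter.
#' @param seed_genes Seed gene ids for networks (`NULL` = the gene with
#'   the smallest DE p per stratum, a stand-in when the curated seeds are
#'   absent from simulated ids).
#' @param sim A [sim_config()] for simulated inputs.
#' @param seed Master seed.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(out_dir = tempfile("thermosex_run_"),
                       counts = NULL, exon_counts = NULL,
                       sample_sheet = NULL, phenotypes = NULL,
                       gene_sets = NULL, trait = NULL,
                       de_alpha = 0.05, de_use_adjusted = TRUE,
                       dsg_fdr = 0.05, corr_alpha = 0.05, cld_alpha = 0.05,
                       beta = 6, k = 19L, partner_edge_floor = 0.1,
                       min_cpm = 1, min_samples = NULL,
                       seed_genes = NULL,
                       sim = NULL, seed = 1L) {
  for (nm in c("de_alpha", "dsg_fdr", "corr_alpha", "cld_alpha")) {
    v <- get(nm)
    if (v <= 0 || v >= 1) stop(nm, " must lie in (0, 1)", call. = FALSE)
  }
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  if (beta <= 0) stop("beta must be positive", call. = FALSE)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, per tissue x stage stratum: differential expression,
#' differential splicing, per-family fold changes, the IR-correlation
#' screen, co-expression seed networks, evidence integration with Venn
#' partitions, and gene-set over-representation; plus the family-level
#' phenotype statistics once. All result tables are written as TSV/JSON
#' under `config$out_dir` and a machine-readable run report is returned
#' (and written as `run_report.json`). Deterministic for a fixed seed and
#' inputs.
#'
#' @param config A [run_config()].
#' @return The run report (invisibly a list), with per-stage row counts
#'   and warnings.
#' @export
run_pipeline <- function(config = run_config()) {
  t0 <- proc.time()[["elapsed"]]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = config[!vapply(config, is.function, TRUE)],
                 stages = list(), warnings = character())
  note <- function(stage, ...) {
    report$stages[[stage]] <<- c(report$stages[[stage]], list(...))
  }

  # ---- inputs ----
  simc <- if (is.null(config$sim)) sim_config(seed = config$seed) else config$sim
  if (is.null(config$counts)) {
    sim <- simulate_counts(simc)
    counts <- sim$gene_counts
    exon_counts <- sim$exon_counts
    sheet <- sim$sample_sheet
  } else {
    sheet <- read_sample_sheet(config$sample_sheet)
    counts <- read_counts(config$counts, "gene", sheet)
    exon_counts <- if (!is.null(config$exon_counts))
      read_counts(config$exon_counts, "exon", sheet) else NULL
  }
  batches <- if (is.null(config$phenotypes)) {
    simulate_phenotypes(simc)$batches
  } else {
    read_phenotypes(config$phenotypes)
  }
  trait <- if (!is.null(config$trait)) config$trait else
    stats::setNames(simc$ir_values, family_labels(simc$n_families))
  annotation <- if (is.null(config$gene_sets)) {
    ann <- simulate_annotation(nrow(counts), n_terms = 50, seed = config$seed)
    ann$gene_sets
  } else {
    read_gmt(config$gene_sets)$gene_sets
  }

  # ---- phenotype statistics ----
  pairs <- family_pairs(batches)
  summ <- summarize_population(pairs, batches, alpha = config$cld_alpha)
  write_tsv(pairs, file.path(config$out_dir, "family_pairs.tsv"))
  write_tsv(summ$summary, file.path(config$out_dir, "population_summary.tsv"))
  rsr_ir <- spearman_correlation(pairs$rsr, pairs$ir)
  write_tsv(data.frame(statistic = "spearman_rsr_vs_ir", rho = rsr_ir$rho,
                       p = rsr_ir$p, n = rsr_ir$n),
            file.path(config$out_dir, "rsr_ir_correlation.tsv"))
  note("phenotypes", n_families = nrow(pairs), rsr_ir_rho = rsr_ir$rho)

  # ---- per-stratum transcriptome chain ----
  strata <- unique(sheet[, c("tissue", "stage_dpf")])
  for (i in seq_len(nrow(strata))) {
    tis <- strata$tissue[i]; stg <- strata$stage_dpf[i]
    tag <- sprintf("%s_%ddpf", tis, stg)
    ssub <- sheet[sheet$tissue == tis & sheet$stage_dpf == stg, , drop = FALSE]
    csub <- counts[, ssub$sample_id, drop = FALSE]

    de <- de_stratum(csub, ssub, alpha = config$de_alpha,
                     use_adjusted = config$de_use_adjusted,
                     min_cpm = config$min_cpm,
                     min_samples = config$min_samples)
    write_tsv(de, file.path(config$out_dir, paste0("de_", tag, ".tsv")))

    ds <- NULL
    if (!is.null(exon_counts)) {
      ds <- splice_test(exon_counts[, c("gene_id", "exon_id", ssub$sample_id)],
                        ssub, fdr = config$dsg_fdr,
                        min_cpm = config$min_cpm,
                        min_samples = config$min_samples)
      write_tsv(ds$genes, file.path(config$out_dir, paste0("ds_", tag, ".tsv")))
    } else {
      report$warnings <- c(report$warnings,
                           sprintf("no exon table: splicing skipped for %s", tag))
    }

    keep <- filter_expressed(csub, config$min_cpm, config$min_samples)
    lc <- cpm(csub[keep, , drop = FALSE], log = TRUE)
    fcm <- family_fold_changes(lc, ssub)
    corr <- trait_correlation(fcm, trait, alpha = config$corr_alpha)
    write_tsv(corr, file.path(config$out_dir, paste0("corr_", tag, ".tsv")))

    ev <- evidence_table(de, if (!is.null(ds)) ds$genes else NULL, corr)
    write_tsv(ev, file.path(config$out_dir, paste0("evidence_", tag, ".tsv")))
    venn <- venn_counts(ev$gene[ev$deg_direction != "none"],
                        ev$gene[ev$dsg],
                        ev$gene[ev$corr_sign != "none"])
    jsonlite::write_json(venn,
                         file.path(config$out_dir, paste0("venn_", tag, ".json")),
                         auto_unbox = TRUE)

    adj <- adjacency_matrix(fcm, beta = config$beta)
    seeds <- config$seed_genes
    if (is.null(seeds)) seeds <- ev$gene[which.min(ev$adj_p)]
    seeds <- intersect(seeds, rownames(adj))
    for (sg in seeds) {
      net <- seed_network(adj, sg, k = config$k, evidence = ev,
                          partner_edge_floor = config$partner_edge_floor)
      write_network(net,
                    file.path(config$out_dir,
                              sprintf("network_%s_%s.graphml", tag, sg)),
                    "graphml")
    }

    enr <- run_categorized(ev, annotation)
    if (length(enr)) {
      write_tsv(do.call(rbind, enr),
                file.path(config$out_dir, paste0("enrichment_", tag, ".tsv")))
    }
    note(paste0("stratum_", tag),
         n_genes_tested = nrow(de), n_filtered = attr(de, "n_filtered"),
         n_deg = sum(de$direction != "none"),
         n_dsg = if (!is.null(ds)) sum(ds$genes$dsg) else NA_integer_,
         n_corr = sum(corr$sign != "none"),
         n_networks = length(seeds),
         venn_union = venn$union_size)
  }

  report$elapsed_s <- proc.time()[["elapsed"]] - t0
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, force = TRUE, digits = NA)
  invisible(report)
}
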