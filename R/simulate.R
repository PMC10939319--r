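#' Simulation configuration for the sex-reversal study design
#'
#' Builds and validates the configuration object used by the synthetic-data
#' generators. Defaults emulate the study design the pipeline targets:
#' 6 full-sib families, each split into a 30 degC control batch and a
#' 36.5 degC high-temperature ("ltherm") batch, sampled in two tissues
#' (gonad, brain) at two stages (15 and 40 dpf), with the family
#' reversal-rate trait vector IR = (18, 34, 73, 26, 100, 12) percent.
#'
#' @param n_families Number of full-sib families (default 6).
#' @param n_genes Number of genes in the count matrices.
#' @param exons_per_gene Integer range (length-2 vector) of exons per gene;
#'   exon counts are drawn uniformly over this range.
#' @param control_male_prob Probability a control fish is male (default 0.5,
#'   the balanced genotypic expectation).
#' @param reversal_prob Probability that a female-fated fish is masculinized
#'   under treatment (default 0.44, matching a mean reversal rate of ~44%).
#' @param survival_probs Length-2 vector of survival probabilities
#'   (control, treated) to 31 dpf.
#' @param n_fish_per_batch Fish stocked per batch.
#' @param lib_size_mean Expected library size per sample (reads).
#' @param nb_dispersion Negative-binomial dispersion phi in
#'   Var = mu + phi mu^2.
#' @param frac_de Fraction of genes with a planted treatment effect.
#' @param de_lfc Magnitude of the planted treatment log2 fold change
#'   (sign randomized per gene).
#' @param frac_ir_linked Fraction of genes whose treatment fold change is
#'   proportional to the family IR.
#' @param ir_slope Planted slope in log2 units per IR percent
#'   (sign randomized per gene).
#' @param frac_ds Fraction of genes with a planted single-exon splicing
#'   effect.
#' @param ds_exon_lfc Log2 fold change applied to the affected exon only.
#' @param ir_values Family reversal rates in percent (length `n_families`).
#' @param seed Master seed; every output table derives its own RNG stream
#'   from it.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_families = 6L,
                       n_genes = 2000L,
                       exons_per_gene = c(2L, 8L),
                       control_male_prob = 0.5,
                       reversal_prob = 0.44,
                       survival_probs = c(0.8, 0.9),
                       n_fish_per_batch = 200L,
                       lib_size_mean = 2e6,
                       nb_dispersion = 0.1,
                       frac_de = 0.05,
                       de_lfc = 2,
                       frac_ir_linked = 0.05,
                       ir_slope = 0.02,
                       frac_ds = 0.05,
                       ds_exon_lfc = 3,
                       ir_values = c(18, 34, 73, 26, 100, 12),
                       seed = 1L) {
  cfg <- list(n_families = as.integer(n_families),
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              control_male_prob = control_male_prob,
              reversal_prob = reversal_prob,
              survival_probs = survival_probs,
              n_fish_per_batch = as.integer(n_fish_per_batch),
              lib_size_mean = lib_size_mean,
              nb_dispersion = nb_dispersion,
              frac_de = frac_de, de_lfc = de_lfc,
              frac_ir_linked = frac_ir_linked, ir_slope = ir_slope,
              frac_ds = frac_ds, ds_exon_lfc = ds_exon_lfc,
              ir_values = ir_values, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  props <- c(control_male_prob = cfg$control_male_prob,
             reversal_prob = cfg$reversal_prob,
             survival_control = cfg$survival_probs[1],
             survival_treated = cfg$survival_probs[2],
             frac_de = cfg$frac_de, frac_ir_linked = cfg$frac_ir_linked,
             frac_ds = cfg$frac_ds)
  bad <- names(props)[props < 0 | props > 1 | is.na(props)]
  if (length(bad)) {
    stop("proportions out of [0, 1]: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (cfg$frac_de + cfg$frac_ir_linked + cfg$frac_ds > 1) {
    stop("planted effect fractions must sum to at most 1", call. = FALSE)
  }
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive", call. = FALSE)
  if (cfg$n_families < 1 || cfg$n_genes < 1 || cfg$n_fish_per_batch < 1) {
    stop("n_families, n_genes and n_fish_per_batch must be positive",
         call. = FALSE)
  }
  if (length(cfg$ir_values) != cfg$n_families) {
    stop(sprintf("ir_values has length %d but n_families is %d",
                 length(cfg$ir_values), cfg$n_families), call. = FALSE)
  }
  if (length(cfg$exons_per_gene) != 2L ||
      cfg$exons_per_gene[1] < 1L ||
      cfg$exons_per_gene[2] < cfg$exons_per_gene[1]) {
    stop("exons_per_gene must be an increasing positive integer range",
         call. = FALSE)
  }
  cfg
}

# deterministic per-table RNG stream split from the master seed, so that
# e.g. enlarging the count matrix never perturbs the phenotype simulation
stream_seed <- function(seed, stream) {
  offsets <- c(phenotypes = 101L, counts = 211L, annotation = 307L,
               acceptance = 401L)
  (as.integer(seed) %% 1000003L) * 2011L + offsets[[stream]]
}

family_labels <- function(n) sprintf("F%02d", seq_len(n))

#' Simulate family-level phenotype batch records
#'
#' For each family, draws one control and one treated batch. Survivors are
#' binomial in the number stocked with the arm-specific survival
#' probability; males among sexed fish are binomial with success probability
#' `control_male_prob` in the control arm and
#' `control_male_prob + (1 - control_male_prob) * reversal_prob` in the
#' treated arm (every female-fated fish is independently masculinized with
#' probability `reversal_prob`). All survivors are sexed.
#'
#' @param config A [sim_config()] object.
#' @return A list with `batches` (phenotype batch table) and `truth`
#'   (list with the generating probabilities).
#' @export
simulate_phenotypes <- function(config) {
  config <- validate_sim_config(config)
  withr_seed(stream_seed(config$seed, "phenotypes"), {
    fams <- family_labels(config$n_families)
    p_ctl <- config$control_male_prob
    p_trt <- p_ctl + (1 - p_ctl) * config$reversal_prob
    rows <- lapply(seq_along(fams), function(i) {
      n <- config$n_fish_per_batch
      alive_c <- stats::rbinom(1L, n, config$survival_probs[1])
      alive_t <- stats::rbinom(1L, n, config$survival_probs[2])
      males_c <- stats::rbinom(1L, alive_c, p_ctl)
      males_t <- stats::rbinom(1L, alive_t, p_trt)
      data.frame(
        population = "SIM", family = rep(fams[i], 2L),
        treatment = c("control", "ltherm"),
        n_stocked = n,
        n_alive_31dpf = c(alive_c, alive_t),
        n_sexed = c(alive_c, alive_t),
        n_males = c(males_c, males_t),
        stringsAsFactors = FALSE
      )
    })
    list(batches = do.call(rbind, rows),
         truth = list(p_male_control = p_ctl, p_male_treated = p_trt,
                      expected_ir = 100 * config$reversal_prob))
  })
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate gene- and exon-level count matrices with planted effects
#'
#' Emulates the full study design: `n_families x 2 treatments x 2 tissues
#' x 2 stages` libraries with no within-condition replicates. Exon counts
#' are generated first from a negative-binomial model and gene counts are
#' their per-gene sums, so the gene/exon consistency the splicing test
#' assumes holds by construction. Baseline gene abundances are log-normal;
#' a fraction of genes carries a treatment log2 fold change (`de_lfc`), a
#' disjoint fraction carries an IR-proportional treatment effect
#' (`ir_slope` log2 units per IR percent), and a third disjoint fraction
#' carries a single-exon splicing effect (`ds_exon_lfc`). Effects are
#' applied in every tissue x stage stratum.
#'
#' @param config A [sim_config()] object.
#' @return A list with `gene_counts` (matrix genes x samples),
#'   `exon_counts` (data frame: gene_id, exon_id, then one column per
#'   sample), `sample_sheet`, and `truth` (planted gene sets with signed
#'   effect sizes).
#' @export
simulate_counts <- function(config) {
  config <- validate_sim_config(config)
  withr_seed(stream_seed(config$seed, "counts"), {
    fams <- family_labels(config$n_families)
    sheet <- expand.grid(treatment = c("control", "ltherm"),
                         family = fams,
                         stage_dpf = c(15L, 40L),
                         tissue = c("gonad", "brain"),
                         stringsAsFactors = FALSE)
    sheet$population <- "SIM"
    sheet$sample_id <- sprintf("S%02d_%s_%s_%s_%02ddpf",
                               seq_len(nrow(sheet)), sheet$family,
                               substr(sheet$treatment, 1, 3),
                               sheet$tissue, sheet$stage_dpf)
    sheet <- sheet[, c("sample_id", "family", "population", "treatment",
                       "tissue", "stage_dpf")]

    ng <- config$n_genes
    genes <- sprintf("G%05d", seq_len(ng))
    n_exons <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]),
                      ng, replace = TRUE)

    # disjoint planted effect classes
    n_de <- round(config$frac_de * ng)
    n_ir <- round(config$frac_ir_linked * ng)
    n_ds <- round(config$frac_ds * ng)
    pick <- sample(ng, n_de + n_ir + n_ds)
    de_idx <- pick[seq_len(n_de)]
    ir_idx <- pick[n_de + seq_len(n_ir)]
    ds_idx <- pick[n_de + n_ir + seq_len(n_ds)]
    de_sign <- sample(c(-1, 1), n_de, replace = TRUE)
    ir_sign <- sample(c(-1, 1), n_ir, replace = TRUE)
    ds_exon <- vapply(ds_idx, function(g) sample.int(n_exons[g], 1L), 1L)

    # baseline abundance: relative expression, log-normal across genes
    base <- stats::rlnorm(ng, meanlog = log(50), sdlog = 1.2)
    exon_prop <- lapply(seq_len(ng), function(g) {
      w <- stats::runif(n_exons[g], 0.5, 1.5)
      w / sum(w)
    })

    ir_by_fam <- stats::setNames(config$ir_values, fams)
    nsamp <- nrow(sheet)
    total_exons <- sum(n_exons)
    exon_gene <- rep(seq_len(ng), n_exons)
    exon_id <- unlist(lapply(n_exons, seq_len), use.names = FALSE)
    exon_mat <- matrix(0L, total_exons, nsamp)

    lfc_gene <- numeric(ng)
    size <- 1 / config$nb_dispersion
    for (s in seq_len(nsamp)) {
      treated <- sheet$treatment[s] == "ltherm"
      lfc_gene[] <- 0
      if (treated) {
        lfc_gene[de_idx] <- de_sign * config$de_lfc
        lfc_gene[ir_idx] <- ir_sign * config$ir_slope *
          ir_by_fam[[sheet$family[s]]]
      }
      mu_gene <- base * 2^lfc_gene
      mu_exon <- mu_gene[exon_gene] * unlist(exon_prop, use.names = FALSE)
      if (treated && n_ds > 0) {
        off <- cumsum(c(0L, n_exons))[ds_idx] + ds_exon
        mu_exon[off] <- mu_exon[off] * 2^config$ds_exon_lfc
      }
      # scale relative abundances to the target library size
      mu_exon <- mu_exon / sum(base) * config$lib_size_mean
      exon_mat[, s] <- as.integer(stats::rnbinom(total_exons, mu = mu_exon,
                                                 size = size))
    }

    gene_mat <- rowsum(exon_mat, exon_gene, reorder = TRUE)
    rownames(gene_mat) <- genes
    colnames(gene_mat) <- sheet$sample_id
    exon_df <- data.frame(gene_id = genes[exon_gene], exon_id = exon_id,
                          stringsAsFactors = FALSE)
    exon_df <- cbind(exon_df, as.data.frame(exon_mat))
    names(exon_df)[-(1:2)] <- sheet$sample_id

    truth <- list(
      de_genes = stats::setNames(de_sign * config$de_lfc, genes[de_idx]),
      ir_linked_genes = stats::setNames(ir_sign * config$ir_slope,
                                        genes[ir_idx]),
      ds_genes = if (n_ds > 0) {
        stats::setNames(lapply(seq_along(ds_idx), function(i) {
          list(exon_id = ds_exon[i], lfc = config$ds_exon_lfc)
        }), genes[ds_idx])
      } else stats::setNames(list(), character())
    )
    list(gene_counts = gene_mat, exon_counts = exon_df,
         sample_sheet = sheet, truth = truth)
  })
}

#' Simulate gene-set annotation and conflicting ID-mapping tables
#'
#' Generates a term-to-gene annotation (GMT-style) with controlled term
#' sizes and several identifier mapping tables (source, from_id, to_id) in
#' which a configurable fraction of identifiers carries a planted 2-vs-1
#' conflict across sources, so the majority-vote resolver has known ground
#' truth.
#'
#' @param n_genes Number of genes to annotate.
#' @param n_terms Number of gene-set terms (`>= 1`).
#' @param sources Number of mapping tables.
#' @param conflict_frac Fraction of identifiers with a planted minority
#'   association (requires `sources >= 3`).
#' @param term_size_range Integer range of genes per term.
#' @param seed RNG seed.
#' @return A list with `gene_sets` (named list of gene-id vectors, plus a
#'   `names` attribute-carrying data frame `terms`), `mapping` (data frame
#'   source/from_id/to_id), and `truth` (named character: majority to_id
#'   per from_id).
#' @export
simulate_annotation <- function(n_genes, n_terms, sources = 3L,
                                conflict_frac = 0, term_size_range = c(5L, 50L),
                                seed = 1L) {
  if (n_terms < 1) stop("n_terms must be at least 1", call. = FALSE)
  if (conflict_frac > 0 && sources < 3) {
    stop("planted 2-vs-1 conflicts need at least 3 sources", call. = FALSE)
  }
  withr_seed(stream_seed(seed, "annotation"), {
    genes <- sprintf("G%05d", seq_len(n_genes))
    sizes <- sample(seq(term_size_range[1], min(term_size_range[2], n_genes)),
                    n_terms, replace = TRUE)
    sets <- lapply(seq_len(n_terms), function(i) sample(genes, sizes[i]))
    names(sets) <- sprintf("T%04d", seq_len(n_terms))
    terms <- data.frame(term_id = names(sets),
                        term_name = sprintf("synthetic process %d",
                                            seq_len(n_terms)),
                        stringsAsFactors = FALSE)

    majority <- stats::setNames(sprintf("X%05d", seq_len(n_genes)), genes)
    n_conf <- round(conflict_frac * n_genes)
    conf <- sample(genes, n_conf)
    rows <- lapply(seq_len(sources), function(s) {
      to <- majority
      if (n_conf > 0 && s == sources) {
        # the last source dissents: 2-vs-1 conflicts on the chosen ids
        to[conf] <- paste0(to[conf], "_alt")
      }
      data.frame(source = sprintf("src%d", s), from_id = genes, to_id = to,
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    list(gene_sets = sets, terms = terms,
         mapping = do.call(rbind, rows),
         truth = majority)
  })
}
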