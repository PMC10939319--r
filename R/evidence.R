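#' Exclusive Venn partition of three gene sets
#'
#' Partitions the union of the DEG, DSG and Corr gene sets into the seven
#' exclusive regions of a three-set Venn diagram.
#'
#' @param deg,dsg,corr Character vectors of gene ids.
#' @return A list with the seven exclusive region counts
#'   (`deg_only`, `dsg_only`, `corr_only`, `deg_dsg`, `deg_corr`,
#'   `dsg_corr`, `all_three`), `union_size`, and the inclusive sizes
#'   `n_deg`, `n_dsg`, `n_corr`.
#' @export
venn_counts <- function(deg, dsg, corr) {
  deg <- unique(deg); dsg <- unique(dsg); corr <- unique(corr)
  u <- union(union(deg, dsg), corr)
  in_deg <- u %in% deg; in_dsg <- u %in% dsg; in_corr <- u %in% corr
  list(deg_only  = sum(in_deg & !in_dsg & !in_corr),
       dsg_only  = sum(!in_deg & in_dsg & !in_corr),
       corr_only = sum(!in_deg & !in_dsg & in_corr),
       deg_dsg   = sum(in_deg & in_dsg & !in_corr),
       deg_corr  = sum(in_deg & !in_dsg & in_corr),
       dsg_corr  = sum(!in_deg & in_dsg & in_corr),
       all_three = sum(in_deg & in_dsg & in_corr),
       union_size = length(u),
       n_deg = length(deg), n_dsg = length(dsg), n_corr = length(corr))
}

#' Render a per-gene evidence status string
#'
#' Combines the three calls into the compact status notation used in the
#' result tables: upper-case for a significant expression call
#' (`↑Exp` / `↓Exp`), lower-case for a non-significant fold
#' change in that direction (`↑exp` / `↓exp`), `+Corr` / `-Corr`
#' for a significant fold-change/IR correlation, and `DSG` for a
#' differential-splicing call, joined with "and".
#'
#' @param deg_direction `"up"`, `"down"` or `"none"`.
#' @param fc_sign Sign of the (possibly non-significant) fold change,
#'   used for the lower-case forms when `deg_direction` is `"none"`.
#' @param corr_sign `"+"`, `"-"` or `"none"`.
#' @param dsg Logical splicing flag.
#' @return Status string.
#' @export
render_status <- function(deg_direction, fc_sign = 1, corr_sign = "none",
                          dsg = FALSE) {
  expr <- switch(deg_direction,
                 up = "↑Exp", down = "↓Exp",
                 none = if (fc_sign >= 0) "↑exp" else "↓exp",
                 stop("deg_direction must be up/down/none", call. = FALSE))
  parts <- expr
  if (corr_sign == "+") parts <- c(parts, "+Corr")
  if (corr_sign == "-") parts <- c(parts, "-Corr")
  if (isTRUE(dsg)) parts <- c(parts, "DSG")
  paste(parts, collapse = " and ")
}

#' Parse an evidence status string back into its three calls
#'
#' Inverse of [render_status()].
#'
#' @param status Status string.
#' @return List with `deg_direction`, `fc_sign`, `corr_sign`, `dsg`.
#' @export
parse_status <- function(status) {
  parts <- strsplit(status, " and ", fixed = TRUE)[[1]]
  expr <- parts[1]
  deg <- switch(expr,
                "↑Exp" = "up", "↓Exp" = "down",
                "↑exp" = "none", "↓exp" = "none",
                stop("unrecognized expression component: ", expr,
                     call. = FALSE))
  fc_sign <- if (expr %in% c("↑Exp", "↑exp")) 1 else -1
  corr <- if ("+Corr" %in% parts) "+" else if ("-Corr" %in% parts) "-" else "none"
  list(deg_direction = deg, fc_sign = fc_sign, corr_sign = corr,
       dsg = "DSG" %in% parts)
}

#' Assemble the per-gene evidence table for one stratum
#'
#' Joins the differential-expression, differential-splicing and
#' IR-correlation results on gene id and renders the status string.
#'
#' @param de [moderate_and_test()] / [de_stratum()] output.
#' @param ds `genes` component of [splice_test()] output (or `NULL`).
#' @param corr [trait_correlation()] output (or `NULL`).
#' @return Data frame: `gene`, `deg_direction`, `logFC`, `adj_p`, `dsg`,
#'   `corr_sign`, `r`, `status`.
#' @export
evidence_table <- function(de, ds = NULL, corr = NULL) {
  out <- data.frame(gene = de$gene, deg_direction = de$direction,
                    logFC = de$logFC, adj_p = de$adj_p,
                    stringsAsFactors = FALSE)
  out$dsg <- FALSE
  if (!is.null(ds) && nrow(ds)) {
    m <- match(out$gene, ds$gene)
    out$dsg[!is.na(m)] <- ds$dsg[m[!is.na(m)]]
  }
  out$corr_sign <- "none"
  out$r <- NA_real_
  if (!is.null(corr) && nrow(corr)) {
    m <- match(out$gene, corr$gene)
    out$corr_sign[!is.na(m)] <- corr$sign[m[!is.na(m)]]
    out$r[!is.na(m)] <- corr$r[m[!is.na(m)]]
  }
  out$status <- mapply(render_status, out$deg_direction,
                       sign(out$logFC), out$corr_sign, out$dsg,
                       USE.NAMES = FALSE)
  out
}

#' Cross-reference curated genes of interest against the evidence table
#'
#' Resolves each curated gene (through an optional synonym map) to at most
#' one evidence-table id and reports its status, correlation and fold
#' change, or "absent".
#'
#' @param evidence [evidence_table()] output.
#' @param curated Character vector of curated gene names. Defaults to the
#'   sexual-differentiation/maturation panel used throughout the analysis.
#' @param synonyms Optional named list mapping a curated name to its
#'   synonym ids; a curated entry resolving to more than one evidence id
#'   is an error.
#' @return Data frame: `curated`, `gene` (resolved id or `NA`), `present`,
#'   `status`, `r`, `logFC`.
#' @export
crossref_genes_of_interest <- function(evidence,
                                       curated = curated_sex_genes(),
                                       synonyms = default_synonyms()) {
  if (!length(curated)) stop("curated list must be non-empty", call. = FALSE)
  rows <- lapply(curated, function(g) {
    cand <- unique(c(g, synonyms[[g]]))
    hit <- evidence$gene[evidence$gene %in% cand]
    if (length(hit) > 1L) {
      stop(sprintf("curated gene '%s' resolves ambiguously to: %s", g,
                   paste(hit, collapse = ", ")), call. = FALSE)
    }
    if (length(hit) == 1L) {
      i <- match(hit, evidence$gene)
      data.frame(curated = g, gene = hit, present = TRUE,
                 status = evidence$status[i], r = evidence$r[i],
                 logFC = evidence$logFC[i], stringsAsFactors = FALSE)
    } else {
      data.frame(curated = g, gene = NA_character_, present = FALSE,
                 status = "absent", r = NA_real_, logFC = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Curated sexual-differentiation/maturation gene panel
#'
#' Genes classically associated with sex determination, differentiation or
#' maturation in tilapia and other teleosts, used to cross-reference the
#' DEG/DSG/Corr lists.
#'
#' @return Character vector of gene names.
#' @export
curated_sex_genes <- function() {
  c("dmrt1", "esr1", "esr2", "cyp11c1", "gth-ri", "gth-rii",
    "hsd11b1Ia(2)", "amh", "dax1", "cyp19a1a", "cyp19a1b", "ara",
    "cyp21a2", "ihcgr", "bmpr2(1)", "bmpr2(2)", "sf1", "foxl2")
}

#' Default seed genes for co-expression networks
#'
#' The ten genes of interest around which seed networks are built.
#'
#' @return Character vector of gene names.
#' @export
default_seed_genes <- function() {
  c("amh", "cyp11c1", "cyp19a1a", "cyp19a1b", "dmrt1", "hsd11b1la",
    "hsd11b1lac(2)", "dax1", "sf1", "hsd11b2")
}

default_synonyms <- function() {
  list("dax1" = "nr0b1", "sf1" = "nr5a1",
       "hsd11b1Ia(2)" = c("hsd11b1la", "hsd11b1lac(2)"))
}

#' Filter the evidence table by a status predicate
#'
#' Returns the genes whose evidence row satisfies `predicate`, ordered by
#' adjusted p then gene id (stable).
#'
#' @param evidence [evidence_table()] output.
#' @param predicate Function of one evidence row (as a list) returning
#'   `TRUE`/`FALSE`; e.g.
#'   `function(e) e$deg_direction != "none" && e$corr_sign != "none"`.
#' @return Character vector of gene ids.
#' @export
filter_by_status <- function(evidence, predicate) {
  keep <- vapply(seq_len(nrow(evidence)),
                 function(i) isTRUE(predicate(as.list(evidence[i, ]))),
                 logical(1))
  sub <- evidence[keep, , drop = FALSE]
  sub$gene[order(sub$adj_p, sub$gene)]
}
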