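#' Majority-vote identifier resolution across mapping tables
#'
#' Combines several identifier mapping tables (columns `source`,
#' `from_id`, `to_id`) and keeps, for each `from_id`, the `to_id`
#' referenced by the most sources. Identifiers whose top associations tie
#' are dropped with a warning, so the result is a function (each `from_id`
#' maps to at most one `to_id`).
#'
#' @param mapping Data frame with columns `source`, `from_id`, `to_id`
#'   (one or several tables row-bound; duplicate triples are collapsed).
#' @return Named character vector: `from_id` -> majority `to_id`.
#' @export
resolve_ids <- function(mapping) {
  need <- c("source", "from_id", "to_id")
  if (!all(need %in% names(mapping))) {
    stop("mapping must have columns source, from_id, to_id", call. = FALSE)
  }
  mapping <- unique(mapping[, need])
  out <- character(); dropped <- character()
  for (f in unique(mapping$from_id)) {
    votes <- table(mapping$to_id[mapping$from_id == f])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) {
      out[f] <- top
    } else {
      dropped <- c(dropped, f)
    }
  }
  if (length(dropped)) {
    warning(sprintf("%d identifier(s) dropped due to tied associations: %s",
                    length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")),
            call. = FALSE)
  }
  out
}

#' Augment a gene-set annotation through orthologs
#'
#' Per gene, unions its native term memberships with the terms annotated
#' to its ortholog in a better-annotated donor species. Genes without an
#' ortholog keep their native annotation unchanged.
#'
#' @param native Named list: term id -> character vector of gene ids.
#' @param ortholog_map Named character vector: gene id -> donor gene id.
#' @param donor Named list: term id -> character vector of donor gene ids.
#' @return Named list of term memberships (union of both sources, on
#'   native gene ids).
#' @export
augment_by_ortholog <- function(native, ortholog_map, donor) {
  out <- native
  for (term in names(donor)) {
    donors <- donor[[term]]
    hits <- names(ortholog_map)[ortholog_map %in% donors]
    if (length(hits)) {
      out[[term]] <- unique(c(out[[term]], hits))
    }
  }
  out[lengths(out) > 0]
}

#' Hypergeometric over-representation test
#'
#' Per term, the upper-tail hypergeometric probability
#' `P(X >= k)` of seeing `k` list genes in a term of size `K` when `n`
#' genes are drawn from a universe of `N`, BH-adjusted across tested
#' terms. Terms outside the size bounds (after intersecting with the
#' universe) are skipped.
#'
#' @param gene_list Character vector of genes of interest (subset of the
#'   universe; genes outside it are dropped).
#' @param universe Character vector of all eligible genes.
#' @param annotation Named list: term id -> gene ids.
#' @param term_names Optional named character vector of term descriptions.
#' @param min_term_size,max_term_size Size bounds on the
#'   universe-intersected term (defaults 5 and 500).
#' @return Data frame: `term`, `name`, `k`, `K`, `n`, `N`, `p`, `adj_p`,
#'   `fold` (`(k/n)/(K/N)`), sorted by p.
#' @export
hypergeom_enrich <- function(gene_list, universe, annotation,
                             term_names = NULL,
                             min_term_size = 5L, max_term_size = 500L) {
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  if (!length(gene_list) || !length(universe)) {
    stop("gene list and universe must be non-empty", call. = FALSE)
  }
  gene_list <- intersect(gene_list, universe)
  n <- length(gene_list); N <- length(universe)
  rows <- lapply(names(annotation), function(term) {
    members <- intersect(unique(annotation[[term]]), universe)
    K <- length(members)
    if (K < min_term_size || K > max_term_size) return(NULL)
    k <- length(intersect(gene_list, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term,
               name = if (!is.null(term_names) && term %in% names(term_names))
                 term_names[[term]] else term,
               k = k, K = K, n = n, N = N, p = p,
               fold = if (K > 0 && n > 0) (k / n) / (K / N) else NA_real_,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(term = character(), name = character(), k = integer(),
                      K = integer(), n = integer(), N = integer(),
                      p = numeric(), adj_p = numeric(), fold = numeric()))
  }
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out <- out[order(out$p, out$term), c("term", "name", "k", "K", "n", "N",
                                       "p", "adj_p", "fold")]
  rownames(out) <- NULL
  out
}

#' Categorized over-representation runs
#'
#' Splits the evidence table into the five reporting categories —
#' upregulated DEGs (`↑Exp`), downregulated DEGs (`↓Exp`), positively and
#' negatively IR-correlated genes (`+Corr`, `-Corr`), and spliced genes
#' (`DSG`) — and runs [hypergeom_enrich()] for each against the shared
#' universe of all genes entering the stratum's analysis. A gene may
#' appear in several categories (e.g. `↑Exp` and `+Corr`). Empty
#' categories are skipped.
#'
#' @param evidence [evidence_table()] output.
#' @param annotation Named list: term id -> gene ids.
#' @param universe Universe gene ids (default: all evidence genes).
#' @param ... Passed to [hypergeom_enrich()].
#' @return Named list of enrichment data frames, one per non-empty
#'   category, each carrying a `category` column.
#' @export
run_categorized <- function(evidence, annotation,
                            universe = evidence$gene, ...) {
  if (!nrow(evidence)) stop("evidence table is empty", call. = FALSE)
  lists <- list(
    "↑Exp" = evidence$gene[evidence$deg_direction == "up"],
    "↓Exp" = evidence$gene[evidence$deg_direction == "down"],
    "+Corr" = evidence$gene[evidence$corr_sign == "+"],
    "-Corr" = evidence$gene[evidence$corr_sign == "-"],
    "DSG" = evidence$gene[evidence$dsg]
  )
  out <- list()
  for (cat in names(lists)) {
    if (!length(lists[[cat]])) next
    res <- hypergeom_enrich(lists[[cat]], universe, annotation, ...)
    if (nrow(res)) res$category <- cat
    out[[cat]] <- res
  }
  out
}
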