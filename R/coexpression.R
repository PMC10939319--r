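#' Unsigned soft-threshold co-expression adjacency
#'
#' Pairwise Pearson correlation of gene fold-change profiles across
#' families, raised elementwise to the soft-threshold power `beta` after
#' taking absolute values: `a_ij = |cor(x_i, x_j)|^beta`. Unsigned, so
#' co-regulation in opposite directions scores as highly as co-regulation
#' in the same direction. Genes with zero profile variance are excluded
#' (reported via the `"dropped_genes"` attribute).
#'
#' @param fcm Fold-change matrix (genes x families), `>= 3` columns.
#' @param beta Soft-threshold power (default 6).
#' @return Symmetric adjacency matrix with unit diagonal, entries in
#'   `[0, 1]`.
#' @export
adjacency_matrix <- function(fcm, beta = 6) {
  if (ncol(fcm) < 3L) stop("need at least 3 family columns", call. = FALSE)
  if (beta <= 0) stop("beta must be positive", call. = FALSE)
  v <- apply(fcm, 1L, stats::var)
  dropped <- rownames(fcm)[v == 0]
  fcm <- fcm[v > 0, , drop = FALSE]
  a <- abs(stats::cor(t(fcm)))^beta
  diag(a) <- 1
  attr(a, "beta") <- beta
  attr(a, "dropped_genes") <- dropped
  a
}

#' Co-expression network around a seed gene
#'
#' Selects the `k` genes with the largest adjacency to the seed (ties
#' broken lexicographically by gene id), connects them to the seed with
#' edges weighted by adjacency, optionally adds partner-partner edges
#' whose adjacency is at least `partner_edge_floor`, and annotates every
#' node with its differential-expression direction and IR-correlation sign
#' from an evidence table.
#'
#' @param adj Adjacency matrix from [adjacency_matrix()].
#' @param seed_gene Gene id of the seed; must be present in `adj`.
#' @param k Number of partners (default 19, giving a 20-node network).
#' @param evidence Optional evidence data frame with columns `gene`,
#'   `deg_direction`, `corr_sign` (missing genes annotated `none`).
#' @param partner_edge_floor Minimum adjacency for partner-partner edges
#'   (default 0.1; `NA` suppresses them).
#' @return An [igraph::graph] with node attributes `deg_direction`,
#'   `corr_sign`, `is_seed` and edge attribute `weight`.
#' @export
seed_network <- function(adj, seed_gene, k = 19L, evidence = NULL,
                         partner_edge_floor = 0.1) {
  genes <- rownames(adj)
  if (!seed_gene %in% genes) {
    near <- genes[grepl(substr(seed_gene, 1, 4), genes, fixed = TRUE)]
    stop(sprintf("seed gene '%s' not in the adjacency matrix%s", seed_gene,
                 if (length(near)) paste0("; near matches: ",
                                          paste(utils::head(near, 5),
                                                collapse = ", ")) else ""),
         call. = FALSE)
  }
  others <- setdiff(genes, seed_gene)
  if (length(others) < k) {
    stop(sprintf("need at least %d non-seed genes, have %d", k,
                 length(others)), call. = FALSE)
  }
  w <- adj[seed_gene, others]
  ord <- order(-w, others) # descending weight, lexicographic tie-break
  partners <- others[ord[seq_len(k)]]

  nodes <- c(seed_gene, partners)
  edges <- data.frame(from = seed_gene, to = partners,
                      weight = adj[seed_gene, partners],
                      stringsAsFactors = FALSE)
  if (!is.na(partner_edge_floor) && k >= 2L) {
    pp <- utils::combn(partners, 2L)
    ww <- adj[cbind(pp[1L, ], pp[2L, ])]
    keepe <- ww >= partner_edge_floor
    if (any(keepe)) {
      edges <- rbind(edges, data.frame(from = pp[1L, keepe],
                                       to = pp[2L, keepe],
                                       weight = ww[keepe],
                                       stringsAsFactors = FALSE))
    }
  }
  look <- function(col) {
    out <- rep("none", length(nodes))
    if (!is.null(evidence)) {
      m <- match(nodes, evidence$gene)
      out[!is.na(m)] <- evidence[[col]][m[!is.na(m)]]
    }
    out
  }
  vert <- data.frame(name = nodes,
                     deg_direction = look("deg_direction"),
                     corr_sign = look("corr_sign"),
                     is_seed = nodes == seed_gene,
                     stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vert)
}
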