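#' Counts-per-million normalization
#'
#' Scales each library to counts per million reads. With `log = TRUE` a
#' prior count is added before taking log2 to keep zero counts finite; the
#' prior is scaled proportionally to each sample's library size (average
#' prior `prior_count`), and the library size is inflated by twice the
#' scaled prior, i.e. `log2((count + prior_s) / (libsize + 2 prior_s) * 1e6)`.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @param log Return log2-CPM instead of CPM.
#' @param prior_count Average prior count added before logging (default 0.5).
#' @param lib_sizes Optional library sizes; defaults to column sums.
#' @return A matrix of (log2-)CPM values with a `"lib_sizes"` attribute.
#' @export
cpm <- function(counts, log = FALSE, prior_count = 0.5, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) {
    bad <- colnames(counts)[lib_sizes <= 0]
    stop("zero library size for sample(s): ",
         paste(if (length(bad)) bad else which(lib_sizes <= 0), collapse = ", "),
         call. = FALSE)
  }
  if (!log) {
    out <- sweep(counts, 2L, lib_sizes, "/") * 1e6
  } else {
    prior_s <- prior_count * lib_sizes / mean(lib_sizes)
    out <- log2(sweep(sweep(counts, 2L, prior_s, "+"), 2L,
                      lib_sizes + 2 * prior_s, "/") * 1e6)
  }
  attr(out, "lib_sizes") <- lib_sizes
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, monotone in sorted order and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs preserved).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
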