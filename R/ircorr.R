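#' Per-family treatment fold-change matrix
#'
#' For one tissue x stage stratum, computes each gene's log2(Ltherm /
#' Control) expression ratio per family as the difference of prior-counted
#' log2-CPM values between the family's treated and control libraries.
#' Families missing either arm are excluded (and reported via the
#' `"dropped_families"` attribute).
#'
#' @param logcpm Log2-CPM matrix over the stratum's samples (see [cpm()]).
#' @param sheet Matching sample-sheet rows.
#' @param tissue,stage_dpf Optional stratum selectors applied to `sheet`
#'   (and the matrix columns) before pairing.
#' @return Genes x families matrix of log2 fold changes, families ordered
#'   by first appearance in the sample sheet.
#' @export
family_fold_changes <- function(logcpm, sheet, tissue = NULL,
                                stage_dpf = NULL) {
  if (!is.null(tissue)) sheet <- sheet[sheet$tissue == tissue, , drop = FALSE]
  if (!is.null(stage_dpf)) sheet <- sheet[sheet$stage_dpf == stage_dpf, , drop = FALSE]
  logcpm <- logcpm[, sheet$sample_id, drop = FALSE]
  fams <- unique(sheet$family)
  cols <- list(); dropped <- character()
  for (f in fams) {
    ctl <- sheet$sample_id[sheet$family == f & sheet$treatment == "control"]
    trt <- sheet$sample_id[sheet$family == f & sheet$treatment == "ltherm"]
    if (length(ctl) == 1L && length(trt) == 1L) {
      cols[[f]] <- logcpm[, trt] - logcpm[, ctl]
    } else {
      dropped <- c(dropped, f)
    }
  }
  if (!length(cols)) {
    stop("no family has both a control and an ltherm sample in this stratum",
         call. = FALSE)
  }
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(logcpm)
  attr(out, "dropped_families") <- dropped
  out
}

#' Correlate gene fold changes with the family reversal rate
#'
#' Per gene, the Pearson correlation between the per-family log2(Ltherm /
#' Control) fold change and the family reversal rate (IR, percent), with a
#' two-sided p-value from `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of
#' freedom. A gene is flagged `+Corr` / `-Corr` when its raw p-value is at
#' or below `alpha`; genes whose fold-change profile has zero variance get
#' an undefined correlation and sign `none`.
#'
#' @param fcm Fold-change matrix from [family_fold_changes()].
#' @param trait Named numeric vector: family -> IR percent. Names must
#'   match the matrix columns (order-free).
#' @param alpha Significance level for the sign call (default 0.05; raw p).
#' @return Data frame: `gene`, `r`, `p`, `sign` (`+`, `-`, `none`).
#' @export
trait_correlation <- function(fcm, trait, alpha = 0.05) {
  if (ncol(fcm) < 3L) stop("need at least 3 families", call. = FALSE)
  if (is.null(names(trait))) {
    stop("trait must be named by family", call. = FALSE)
  }
  miss <- setdiff(colnames(fcm), names(trait))
  if (length(miss)) {
    stop("trait is missing families: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ir <- trait[colnames(fcm)]
  if (stats::sd(ir) == 0) stop("trait is constant across families",
                               call. = FALSE)
  n <- ncol(fcm)
  ir_c <- ir - mean(ir)
  x_c <- fcm - rowMeans(fcm)
  denom <- sqrt(rowSums(x_c^2) * sum(ir_c^2))
  r <- as.vector(x_c %*% ir_c) / denom
  zero_var <- rowSums(x_c^2) == 0
  r[zero_var] <- NA_real_
  r_clip <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- r_clip * sqrt((n - 2) / (1 - r_clip^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[zero_var] <- NA_real_
  sign <- ifelse(!is.na(p) & p <= alpha & r > 0, "+",
                 ifelse(!is.na(p) & p <= alpha & r < 0, "-", "none"))
  data.frame(gene = rownames(fcm), r = r, p = p, sign = sign,
             stringsAsFactors = FALSE, row.names = NULL)
}
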