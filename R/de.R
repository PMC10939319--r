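#' Gene-wise weighted least squares
#'
#' Fits the same linear model to every gene (row) of a log2-CPM matrix by
#' weighted least squares. With unit weights this is ordinary least
#' squares. Returns everything moderation needs: coefficients, unscaled
#' standard errors (the square roots of the diagonal of `(X'WX)^{-1}`),
#' residual standard deviations and residual degrees of freedom.
#'
#' @param logcpm Numeric matrix, genes x samples.
#' @param design Design matrix, samples x coefficients, full rank.
#' @param weights Optional positive weights, genes x samples (or `NULL`
#'   for unit weights).
#' @return A list of class `"gene_fit"` with `coefficients`,
#'   `stdev_unscaled` (both genes x coefficients), `sigma`, `df_residual`,
#'   `fitted`, `design`.
#' @export
fit_weighted_lm <- function(logcpm, design, weights = NULL) {
  logcpm <- as.matrix(logcpm)
  design <- as.matrix(design)
  n <- ncol(logcpm); p <- ncol(design)
  if (nrow(design) != n) {
    stop("design must have one row per sample", call. = FALSE)
  }
  qrd <- qr(design)
  if (qrd$rank < p) {
    aliased <- colnames(design)[qrd$pivot[(qrd$rank + 1):p]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  if (n - p < 1) stop("at least 1 residual degree of freedom required",
                      call. = FALSE)
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    if (!all(dim(weights) == dim(logcpm))) {
      stop("weights must match the dimensions of logcpm", call. = FALSE)
    }
    if (any(weights <= 0) || any(!is.finite(weights))) {
      stop("weights must be positive and finite", call. = FALSE)
    }
  }
  ng <- nrow(logcpm)
  coefs <- matrix(NA_real_, ng, p, dimnames = list(rownames(logcpm),
                                                   colnames(design)))
  stdev <- coefs
  sigma <- numeric(ng)
  fitted <- matrix(NA_real_, ng, n, dimnames = dimnames(logcpm))
  for (g in seq_len(ng)) {
    y <- logcpm[g, ]
    if (is.null(weights)) {
      fit <- stats::lm.fit(design, y)
      xtx_inv <- chol2inv(qr.R(fit$qr))
    } else {
      w <- weights[g, ]
      fit <- stats::lm.wfit(design, y, w)
      xtx_inv <- chol2inv(chol(crossprod(design * sqrt(w))))
    }
    coefs[g, ] <- fit$coefficients
    stdev[g, ] <- sqrt(diag(xtx_inv))
    fitted[g, ] <- y - fit$residuals
    rss <- if (is.null(weights)) sum(fit$residuals^2)
           else sum(weights[g, ] * fit$residuals^2)
    sigma[g] <- sqrt(rss / (n - p))
  }
  structure(list(coefficients = coefs, stdev_unscaled = stdev,
                 sigma = sigma, df_residual = rep(n - p, ng),
                 fitted = fitted, design = design),
            class = "gene_fit")
}

#' Mean-variance precision weights for count-derived log2-CPM
#'
#' Estimates per-observation precision weights from the empirical
#' mean-variance relationship of log2-CPM values, in the style of the
#' voom procedure: fit the design by OLS, regress the square root of each
#' gene's residual standard deviation on its mean log2 count with lowess,
#' evaluate the trend at each observation's fitted log2 count, and use the
#' inverse fourth power of the predicted value as the weight.
#'
#' @param logcpm Log2-CPM matrix carrying a `"lib_sizes"` attribute (as
#'   produced by [cpm()] with `log = TRUE`), genes x samples.
#' @param design Design matrix.
#' @param span Lowess span (default 0.5).
#' @param min_genes Minimum number of genes for a stable trend; below this
#'   unit weights are returned with a warning (default 50).
#' @return A list with `weights` (genes x samples, positive, finite) and
#'   `trend` (data frame `x` = mean log2 count, `y` = predicted sqrt-sd).
#' @export
estimate_precision_weights <- function(logcpm, design, span = 0.5,
                                       min_genes = 50L) {
  logcpm <- as.matrix(logcpm)
  lib_sizes <- attr(logcpm, "lib_sizes")
  if (is.null(lib_sizes)) {
    stop("logcpm must carry a 'lib_sizes' attribute (see cpm(log = TRUE))",
         call. = FALSE)
  }
  if (nrow(logcpm) < min_genes) {
    warning(sprintf(
      "only %d genes (< %d): falling back to unit precision weights",
      nrow(logcpm), min_genes), call. = FALSE)
    w <- matrix(1, nrow(logcpm), ncol(logcpm), dimnames = dimnames(logcpm))
    return(list(weights = w, trend = NULL))
  }
  fit <- fit_weighted_lm(logcpm, design)
  # abundance axis: mean log2 count per gene
  log_lib <- log2(lib_sizes + 1)
  sx <- rowMeans(logcpm) + mean(log_lib) - log2(1e6)
  sy <- sqrt(fit$sigma)
  lo <- stats::lowess(sx, sy, f = span)
  # per-observation fitted log2 count
  fitted_logcount <- sweep(fit$fitted, 2L, log_lib, "+") - log2(1e6)
  pred <- stats::approx(lo$x, lo$y, xout = as.vector(fitted_logcount),
                        rule = 2, ties = "ordered")$y
  pred <- pmax(pred, 1e-6)
  w <- matrix(pred^(-4), nrow(logcpm), ncol(logcpm),
              dimnames = dimnames(logcpm))
  list(weights = w, trend = data.frame(x = lo$x, y = lo$y))
}

# Newton solve of trigamma(x) = y (vectorized), as used for the prior
# degrees of freedom of the scaled-F model
trigamma_inverse <- function(y) {
  out <- y
  lo <- y < 1e-7; hi <- y > 1e7
  out[lo] <- 1 / sqrt(y[lo])
  out[hi] <- 1 / y[hi]
  mid <- !(lo | hi)
  x <- 0.5 + 1 / y[mid]
  if (any(mid)) {
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (max(-dif / x) < 1e-8) break
    }
    out[mid] <- x
  }
  out
}

#' Squeeze gene-wise variances towards a common prior
#'
#' Empirical-Bayes moderation of gene-wise residual variances: the log
#' variances are matched to a scaled-F model by their first two moments
#' (digamma/trigamma inversion), yielding a prior variance `s0^2` with
#' prior degrees of freedom `d0`; each gene's posterior variance is the
#' degrees-of-freedom-weighted convex combination
#' `(d0 s0^2 + d s^2_g) / (d0 + d)`.
#'
#' @param s2 Gene-wise residual variances (non-negative).
#' @param df Residual degrees of freedom (scalar or per-gene).
#' @return A list with `var_post`, `var_prior` (`s0^2`), `df_prior`
#'   (`d0`, capped at 1e6 when the trigamma inversion indicates full
#'   pooling).
#' @export
squeeze_var <- function(s2, df) {
  if (length(df) == 1L) df <- rep(df, length(s2))
  pos <- s2 > 0
  if (!any(pos)) {
    stop("all residual variances are zero; moderation is undefined",
         call. = FALSE)
  }
  z <- log(s2[pos])
  e <- z - digamma(df[pos] / 2) + log(df[pos] / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df[pos] / 2))
  if (is.na(evar) || evar <= 0) {
    d0 <- 1e6
    s02 <- exp(emean)
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    if (!is.finite(d0) || d0 > 1e6) d0 <- 1e6
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  var_post <- (d0 * s02 + df * s2) / (d0 + df)
  list(var_post = var_post, var_prior = s02, df_prior = d0)
}

#' Moderated t-tests on a model coefficient
#'
#' Applies empirical-Bayes variance moderation to a [fit_weighted_lm()]
#' fit and tests the selected coefficient: moderated
#' `t = beta / (se_unscaled * s_post)` on `d0 + d_g` degrees of freedom,
#' two-sided p, Benjamini-Hochberg adjustment, and a direction call at the
#' chosen threshold.
#'
#' @param fit A `"gene_fit"` object.
#' @param coef Name or index of the coefficient to test.
#' @param alpha Significance threshold for the DEG call (default 0.05).
#' @param use_adjusted Call DEGs on BH-adjusted p (default) rather than
#'   raw p.
#' @param df_prior_override Optional forced prior degrees of freedom
#'   (e.g. 0 recovers the ordinary t-test; used for diagnostics).
#' @return A data frame: `gene`, `logFC`, `t`, `p`, `adj_p`, `direction`
#'   (`up`/`down`/`none`), plus attributes `df_prior`, `var_prior`,
#'   `df_total`.
#' @export
moderate_and_test <- function(fit, coef = "treatmentltherm", alpha = 0.05,
                              use_adjusted = TRUE,
                              df_prior_override = NULL) {
  if (nrow(fit$coefficients) < 2L) {
    stop("moderation needs several genes", call. = FALSE)
  }
  if (is.character(coef) && !coef %in% colnames(fit$coefficients)) {
    stop(sprintf("coefficient '%s' not in the fit (have: %s)", coef,
                 paste(colnames(fit$coefficients), collapse = ", ")),
         call. = FALSE)
  }
  beta <- fit$coefficients[, coef]
  se_u <- fit$stdev_unscaled[, coef]
  s2 <- fit$sigma^2
  df <- fit$df_residual
  if (!is.null(df_prior_override)) {
    d0 <- df_prior_override
    if (d0 == 0) {
      var_post <- s2
      s02 <- NA_real_
    } else {
      sq <- squeeze_var(s2, df)
      var_post <- (d0 * sq$var_prior + df * s2) / (d0 + df)
      s02 <- sq$var_prior
    }
  } else {
    sq <- squeeze_var(s2, df)
    var_post <- sq$var_post
    d0 <- sq$df_prior
    s02 <- sq$var_prior
  }
  df_total <- df + d0
  tstat <- beta / (se_u * sqrt(var_post))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  adj <- bh_adjust(p)
  crit <- if (use_adjusted) adj else p
  direction <- ifelse(crit <= alpha & beta > 0, "up",
                      ifelse(crit <= alpha & beta < 0, "down", "none"))
  out <- data.frame(gene = rownames(fit$coefficients), logFC = beta,
                    t = tstat, p = p, adj_p = adj, direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "df_prior") <- d0
  attr(out, "var_prior") <- s02
  attr(out, "df_total") <- df_total
  out
}

#' Paired treated/control design matrix for one stratum
#'
#' Builds the intercept + family-block + treatment design for a tissue x
#' stage stratum with one control and one ltherm library per family (12
#' samples for 6 families; 5 residual degrees of freedom).
#'
#' @param sheet Sample sheet rows of one stratum.
#' @return Design matrix with the treatment effect as coefficient
#'   `treatmentltherm`.
#' @export
paired_design <- function(sheet) {
  fam <- factor(sheet$family)
  treatment <- factor(sheet$treatment, levels = c("control", "ltherm"))
  stats::model.matrix(~ family + treatment,
                      data = data.frame(family = fam, treatment = treatment))
}

#' Filter weakly expressed genes
#'
#' Keeps genes with CPM at or above `min_cpm` in at least `min_samples`
#' libraries of the stratum (default: half of them).
#'
#' @param counts Count matrix for one stratum.
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples Minimum number of libraries meeting it (default
#'   `ncol/2`).
#' @return Logical vector over genes.
#' @export
filter_expressed <- function(counts, min_cpm = 1, min_samples = NULL) {
  if (is.null(min_samples)) min_samples <- ncol(counts) / 2
  rowSums(cpm(counts) >= min_cpm) >= min_samples
}

#' Full differential-expression pipeline for one stratum
#'
#' Filters weakly expressed genes, computes log2-CPM, estimates
#' mean-variance precision weights, fits the paired family + treatment
#' model and reports moderated treatment tests.
#'
#' @param counts Gene count matrix (stratum samples only).
#' @param sheet Matching sample-sheet rows.
#' @param alpha,use_adjusted DEG call threshold and scale (see
#'   [moderate_and_test()]).
#' @param min_cpm,min_samples Expression filter (see [filter_expressed()]).
#' @param prior_count Prior count for log2-CPM.
#' @return The [moderate_and_test()] data frame for the treatment
#'   coefficient, with attribute `n_filtered`.
#' @export
de_stratum <- function(counts, sheet, alpha = 0.05, use_adjusted = TRUE,
                       min_cpm = 1, min_samples = NULL, prior_count = 0.5) {
  stopifnot(ncol(counts) == nrow(sheet))
  keep <- filter_expressed(counts, min_cpm, min_samples)
  counts <- counts[keep, , drop = FALSE]
  lc <- cpm(counts, log = TRUE, prior_count = prior_count)
  design <- paired_design(sheet)
  w <- estimate_precision_weights(lc, design)
  fit <- fit_weighted_lm(lc, design, weights = w$weights)
  res <- moderate_and_test(fit, coef = "treatmentltherm", alpha = alpha,
                           use_adjusted = use_adjusted)
  attr(res, "n_filtered") <- sum(!keep)
  res
}
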