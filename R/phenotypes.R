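#' Inversion (sex-reversal) rate
#'
#' Fraction (in percent) of presumptive females masculinized by the
#' high-temperature treatment, computed from the male proportions of a
#' treated and a control batch:
#' \deqn{IR = 100 (SR_t - SR_c) / (1 - SR_c)}
#' where \eqn{SR_t} is the male proportion in the treated batch and
#' \eqn{SR_c} in the control batch. Negative values (a treated batch less
#' male-biased than its control) are reported as-is, not clamped.
#'
#' @param sr_treated Male proportion in the treated batch, in `[0, 1]`.
#' @param sr_control Male proportion in the control batch, in `[0, 1)`.
#' @return Inversion rate in percent (`<= 100`, possibly negative).
#' @examples
#' inversion_rate(1.00, 0.50) # 100: an all-male treated batch
#' inversion_rate(0.88, 0.65)
#' @export
inversion_rate <- function(sr_treated, sr_control) {
  check_proportion(sr_treated, "sr_treated")
  check_proportion(sr_control, "sr_control")
  if (any(sr_control == 1)) {
    stop("inversion rate is undefined when the control batch is 100% male",
         call. = FALSE)
  }
  100 * (sr_treated - sr_control) / (1 - sr_control)
}

#' Relative survival rate
#'
#' Same normalized-difference statistic as [inversion_rate()] applied to the
#' survival proportions of the treated and control batches at the end of the
#' treatment window (31 dpf):
#' \deqn{RSR = 100 (SrvlR_t - SrvlR_c) / (1 - SrvlR_c)}
#'
#' @param s_treated Survival proportion in the treated batch, in `[0, 1]`.
#' @param s_control Survival proportion in the control batch, in `[0, 1)`.
#' @return Relative survival rate in percent (`<= 100`, possibly negative).
#' @export
relative_survival_rate <- function(s_treated, s_control) {
  check_proportion(s_treated, "s_treated")
  check_proportion(s_control, "s_control")
  if (any(s_control == 1)) {
    stop("relative survival rate is undefined when control survival is 1",
         call. = FALSE)
  }
  100 * (s_treated - s_control) / (1 - s_control)
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be a proportion in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact conditional test used for the intra-family control-vs-treated
#' comparisons of male ratio and survival. The two-sided p-value follows the
#' probability-mass convention: the sum of hypergeometric probabilities of
#' all tables with the observed margins whose probability does not exceed
#' that of the observed table (with a small relative tolerance for ties).
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise
#'   (`a`,`b` first row; `c`,`d` second row).
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_2x2(3, 1, 1, 3) # 34/70
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all row and column margins must be positive", call. = FALSE)
  }
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Exact binomial test of a sex ratio against 50:50
#'
#' Tests whether the observed number of males among sexed fish departs from
#' the theoretically expected balanced sex ratio. Two-sided p by the
#' probability-mass convention (outcomes no more probable than the observed
#' count under `p = 0.5`).
#'
#' @param n_males Observed number of males.
#' @param n_sexed Total number of sexed fish (`>= 1`).
#' @return Two-sided p-value.
#' @export
binomial_sexratio_test <- function(n_males, n_sexed) {
  if (n_sexed < 1 || n_males < 0 || n_males != round(n_males) ||
      n_sexed != round(n_sexed)) {
    stop("n_males and n_sexed must be integers with n_sexed >= 1", call. = FALSE)
  }
  if (n_males > n_sexed) {
    stop("n_males cannot exceed n_sexed", call. = FALSE)
  }
  stats::binom.test(n_males, n_sexed, p = 0.5,
                    alternative = "two.sided")$p.value
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rank correlation on mid-ranks (average ranks for ties). For `n <= 7` the
#' two-sided p-value is computed by exhaustive enumeration of all
#' permutations of one margin (probability of `|rho|` at least as extreme as
#' observed under the permutation null); for larger `n` the usual
#' t-approximation on `n - 2` degrees of freedom is used.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return A list with elements `rho`, `p`, `n`, `method`, and `defined`
#'   (`FALSE` with `rho = NA` when either margin has zero rank variance).
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not supported", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n,
                method = "undefined", defined = FALSE))
  }
  rho <- stats::cor(rx, ry)
  if (n <= 7L) {
    perms <- permutations_of(n)
    # permutation null: shuffle the y ranks, keep x ranks fixed
    rhos <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
    eps <- 1e-12
    p <- mean(abs(rhos) >= abs(rho) - eps)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method, defined = TRUE)
}

# all n! permutations of 1..n as a matrix (rows); n <= 7 so at most 5040 rows
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Build family control/treated pairs with IR, RSR and per-family tests
#'
#' Pairs each family's control and treated batch records and computes the
#' per-family statistics: male ratios, survival rates, inversion rate,
#' relative survival rate, the Fisher exact test comparing sex ratios
#' between arms, and the binomial test of the control sex ratio against
#' 50:50.
#'
#' @param batches A data frame of batch records with columns `population`,
#'   `family`, `treatment` (`"control"` or `"ltherm"`), `n_stocked`,
#'   `n_alive_31dpf`, `n_sexed`, `n_males`.
#' @return A data frame with one row per family: male ratios and survival
#'   per arm, `ir`, `rsr`, `fisher_p`, `binom_p`.
#' @export
family_pairs <- function(batches) {
  validate_batches(batches)
  fams <- unique(batches$family)
  rows <- lapply(fams, function(f) {
    sub <- batches[batches$family == f, , drop = FALSE]
    ctl <- sub[sub$treatment == "control", , drop = FALSE]
    trt <- sub[sub$treatment == "ltherm", , drop = FALSE]
    if (nrow(ctl) != 1L || nrow(trt) != 1L) {
      stop(sprintf("family '%s' must have exactly one control and one ltherm batch", f),
           call. = FALSE)
    }
    sr_c <- ctl$n_males / ctl$n_sexed
    sr_t <- trt$n_males / trt$n_sexed
    sv_c <- ctl$n_alive_31dpf / ctl$n_stocked
    sv_t <- trt$n_alive_31dpf / trt$n_stocked
    data.frame(
      population = ctl$population, family = f,
      sr_control = sr_c, sr_treated = sr_t,
      surv_control = sv_c, surv_treated = sv_t,
      ir  = if (sr_c < 1) inversion_rate(sr_t, sr_c) else NA_real_,
      rsr = if (sv_c < 1) relative_survival_rate(sv_t, sv_c) else NA_real_,
      fisher_p = fisher_exact_2x2(trt$n_males, trt$n_sexed - trt$n_males,
                                  ctl$n_males, ctl$n_sexed - ctl$n_males),
      binom_p = binomial_sexratio_test(ctl$n_males, ctl$n_sexed),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

validate_batches <- function(batches) {
  need <- c("population", "family", "treatment", "n_stocked",
            "n_alive_31dpf", "n_sexed", "n_males")
  miss <- setdiff(need, names(batches))
  if (length(miss)) {
    stop("batch table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(batches$treatment %in% c("control", "ltherm"))) {
    bad <- which(!batches$treatment %in% c("control", "ltherm"))[1]
    stop(sprintf("invalid treatment label in row %d: '%s'", bad,
                 batches$treatment[bad]), call. = FALSE)
  }
  if (any(batches$n_males > batches$n_sexed)) {
    stop("n_males exceeds n_sexed in at least one batch", call. = FALSE)
  }
  if (any(batches$n_alive_31dpf > batches$n_stocked)) {
    stop("n_alive_31dpf exceeds n_stocked in at least one batch", call. = FALSE)
  }
  invisible(batches)
}

#' Compare group proportions with a binomial-logit model
#'
#' Fits pairwise logistic regressions on per-batch successes/failures,
#' tests each pair by a likelihood-ratio test, adjusts p-values by
#' Benjamini-Hochberg, and summarizes the decisions with a compact letter
#' display (two groups share a letter iff their adjusted p exceeds `alpha`).
#' When a pair exhibits complete separation (a group at proportion 0 or 1),
#' the pair falls back to the exact Fisher test and is flagged in the
#' output.
#'
#' @param successes,totals Integer vectors, one entry per batch.
#' @param grouping Factor (or coercible) of the same length assigning each
#'   batch to a group.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return A list with `pairs` (data frame: group1, group2, p, adj_p,
#'   method) and `letters` (named character vector per group).
#' @export
compare_groups_logistic <- function(successes, totals, grouping, alpha = 0.05) {
  grouping <- factor(grouping)
  if (nlevels(grouping) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (length(successes) != length(totals) ||
      length(successes) != length(grouping)) {
    stop("successes, totals and grouping must have equal length", call. = FALSE)
  }
  if (any(totals <= 0)) stop("all batch totals must be positive", call. = FALSE)
  lev <- levels(grouping)
  combos <- utils::combn(lev, 2L)
  res <- data.frame(group1 = combos[1L, ], group2 = combos[2L, ],
                    p = NA_real_, method = "lrt",
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(combos))) {
    sel <- grouping %in% combos[, i]
    s <- successes[sel]; t <- totals[sel]
    g <- droplevels(grouping[sel])
    agg_s <- tapply(s, g, sum); agg_t <- tapply(t, g, sum)
    separated <- any(agg_s == 0) || any(agg_s == agg_t)
    if (separated) {
      res$p[i] <- fisher_exact_2x2(agg_s[1L], agg_t[1L] - agg_s[1L],
                                   agg_s[2L], agg_t[2L] - agg_s[2L])
      res$method[i] <- "fisher (separation fallback)"
    } else {
      fit1 <- stats::glm(cbind(s, t - s) ~ g, family = stats::binomial())
      fit0 <- stats::glm(cbind(s, t - s) ~ 1, family = stats::binomial())
      res$p[i] <- stats::anova(fit0, fit1, test = "LRT")[2L, "Pr(>Chi)"]
    }
  }
  res$adj_p <- bh_adjust(res$p)
  sig <- matrix(FALSE, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_len(nrow(res))) {
    isig <- res$adj_p[i] <= alpha
    sig[res$group1[i], res$group2[i]] <- isig
    sig[res$group2[i], res$group1[i]] <- isig
  }
  list(pairs = res[, c("group1", "group2", "p", "adj_p", "method")],
       letters = compact_letter_display(sig))
}

# insert-and-absorb compact letter display from a symmetric logical
# "significantly different" matrix; groups share a letter iff not significant
compact_letter_display <- function(sig) {
  lev <- rownames(sig)
  sets <- list(lev)
  for (i in seq_along(lev)) {
    for (j in seq_along(lev)) {
      if (j <= i || !sig[i, j]) next
      for (k in seq_along(sets)) {
        s <- sets[[k]]
        if (all(c(lev[i], lev[j]) %in% s)) {
          sets[[k]] <- setdiff(s, lev[i])
          sets[[length(sets) + 1L]] <- setdiff(s, lev[j])
        }
      }
      # absorb: drop sets contained in another set
      keep <- rep(TRUE, length(sets))
      for (a in seq_along(sets)) {
        for (b in seq_along(sets)) {
          if (a != b && keep[b] &&
              all(sets[[a]] %in% sets[[b]]) &&
              (length(sets[[a]]) < length(sets[[b]]) || a > b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      sets <- sets[keep]
    }
  }
  # order letter sets by their first group for stable output
  ord <- order(vapply(sets, function(s) min(match(s, lev)), 1))
  sets <- sets[ord]
  out <- stats::setNames(rep("", length(lev)), lev)
  for (k in seq_along(sets)) {
    for (g in sets[[k]]) out[g] <- paste0(out[g], letters[k])
  }
  out
}

#' Summarize male ratios, IR and RSR per population
#'
#' Produces the population-by-treatment summary of male ratios (mean, sample
#' SD, median and quartiles by linear interpolation) plus the mean inversion
#' and relative survival rate per population, in the layout of a
#' per-population phenotype summary table.
#'
#' @param pairs Data frame from [family_pairs()].
#' @param batches Original batch table (for sexed-fish totals).
#' @param alpha Significance level for group letters.
#' @return A list with `summary` (one row per population x treatment) and
#'   `ir_rsr` (one row per population: mean/sd of IR and RSR).
#' @export
summarize_population <- function(pairs, batches = NULL, alpha = 0.05) {
  if (nrow(pairs) < 1L) stop("need at least one family", call. = FALSE)
  pops <- unique(pairs$population)
  grid <- expand.grid(population = pops,
                      treatment = c("control", "ltherm"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- grid$population[i]; tr <- grid$treatment[i]
    vals <- if (tr == "control") {
      100 * pairs$sr_control[pairs$population == p]
    } else {
      100 * pairs$sr_treated[pairs$population == p]
    }
    n_sexed <- if (is.null(batches)) NA_integer_ else
      sum(batches$n_sexed[batches$population == p & batches$treatment == tr])
    q <- stats::quantile(vals, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(population = p, treatment = tr,
               n_families = length(vals), n_sexed = n_sexed,
               mean = mean(vals),
               sd = if (length(vals) > 1) stats::sd(vals) else 0,
               p25 = q[1], median = q[2], p75 = q[3],
               stringsAsFactors = FALSE)
  })
  summ <- do.call(rbind, rows)
  # group letters from the logistic comparison of population x treatment cells
  if (!is.null(batches)) {
    cell <- interaction(batches$population, batches$treatment, sep = ":")
    cmp <- compare_groups_logistic(batches$n_males, batches$n_sexed, cell,
                                   alpha = alpha)
    summ$letters <- cmp$letters[paste(summ$population, summ$treatment, sep = ":")]
  } else {
    summ$letters <- "a"
  }
  ir_rsr <- do.call(rbind, lapply(pops, function(p) {
    ir <- pairs$ir[pairs$population == p]
    rsr <- pairs$rsr[pairs$population == p]
    data.frame(population = p,
               mean_ir = mean(ir, na.rm = TRUE),
               sd_ir = if (sum(!is.na(ir)) > 1) stats::sd(ir, na.rm = TRUE) else 0,
               mean_rsr = mean(rsr, na.rm = TRUE),
               sd_rsr = if (sum(!is.na(rsr)) > 1) stats::sd(rsr, na.rm = TRUE) else 0,
               stringsAsFactors = FALSE)
  }))
  list(summary = summ, ir_rsr = ir_rsr)
}
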