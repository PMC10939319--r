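test_that("inversion and relative survival rates follow the display equations", {
  expect_equal(inversion_rate(1.00, 0.50), 100)
  expect_equal(inversion_rate(0.88, 0.65), 100 * (0.88 - 0.65) / 0.35)
  expect_equal(relative_survival_rate(0.95, 0.81), 100 * 0.14 / 0.19)
  expect_equal(relative_survival_rate(1.0, 0.3), 100)
  # no-effect input maps to zero; values may go negative, never above 100
  for (x in c(0, 0.25, 0.6, 0.99)) {
    expect_equal(inversion_rate(x, x), 0)
    expect_equal(relative_survival_rate(x, x), 0)
  }
  expect_lt(inversion_rate(0.3, 0.6), 0)
  # strictly increasing in the treated proportion, bounded by 100
  sr <- seq(0, 1, by = 0.1)
  ir <- inversion_rate(sr, 0.4)
  expect_true(all(diff(ir) > 0))
  expect_true(all(ir <= 100))
  expect_error(inversion_rate(0.5, 1), "undefined")
  expect_error(relative_survival_rate(0.5, 1), "undefined")
  expect_error(inversion_rate(1.2, 0.5), "proportion")
})

test_that("Fisher exact test equals the hypergeometric enumeration oracle", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-10)
  expect_equal(fisher_exact_2x2(3, 1, 1, 3), 34 / 70, tolerance = 1e-10)
  set.seed(42)
  for (i in 1:60) {
    cells <- rpois(4, lambda = sample(3:12, 1))
    cells <- pmin(cells, 30)
    tab <- matrix(cells, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(cells[1], cells[3], cells[2], cells[4]),
                 fisher_enum_oracle(cells[1], cells[3], cells[2], cells[4]),
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(0, 0, 3, 4), "margins")
})

test_that("binomial sex-ratio test is exact and symmetric", {
  expect_equal(binomial_sexratio_test(10, 20), 1)
  expect_equal(binomial_sexratio_test(20, 20), 2 * 0.5^20, tolerance = 1e-10)
  expect_equal(binomial_sexratio_test(15, 20), 2 * 21700 / 2^20,
               tolerance = 1e-10)
  for (n in c(7, 12, 25)) {
    for (k in 0:n) {
      expect_equal(binomial_sexratio_test(k, n),
                   binomial_sexratio_test(n - k, n))
    }
  }
  expect_error(binomial_sexratio_test(5, 4), "exceed")
})

test_that("Spearman correlation matches exhaustive permutation enumeration", {
  r <- spearman_correlation(1:4, c(10, 8, 5, 1))
  expect_equal(r$rho, -1) # monotone decreasing, as in a 4-family panel
  expect_equal(spearman_correlation(1:5, (1:5)^3)$rho, 1)
  expect_equal(spearman_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho, 0.6)
  # exact p equals the two-sided permutation tail; cross-check vs cor.test
  set.seed(7)
  for (n in c(4, 5, 6)) {
    x <- rnorm(n); y <- rnorm(n)
    mine <- spearman_correlation(x, y)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = TRUE))
    expect_equal(mine$rho, unname(ct$estimate))
    expect_equal(mine$p, ct$p.value, tolerance = 1e-10)
  }
  # ties are mid-ranked and zero rank variance is flagged, not silent
  expect_false(spearman_correlation(c(1, 1, 1, 1), 1:4)$defined)
  expect_equal(spearman_correlation(c(1, 2, 2, 3), c(4, 5, 5, 6))$rho, 1)
})

test_that("logistic group comparison produces a consistent letter display", {
  # identical proportions, equal n: one shared letter
  cmp <- compare_groups_logistic(c(50, 50), c(100, 100), c("A", "B"))
  expect_equal(unname(cmp$letters["A"]), unname(cmp$letters["B"]))
  # overwhelming difference: disjoint letters
  cmp <- compare_groups_logistic(c(10, 190), c(200, 200), c("A", "B"))
  expect_false(any(strsplit(cmp$letters["A"], "")[[1]] %in%
                     strsplit(cmp$letters["B"], "")[[1]]))
  # separation falls back to the exact Fisher test and is recorded
  cmp <- compare_groups_logistic(c(0, 10), c(20, 20), c("A", "B"))
  expect_match(cmp$pairs$method[1], "fisher")
  # two-group decisions agree with the Fisher test at alpha = 0.05
  set.seed(11)
  agree <- 0
  for (i in 1:100) {
    n <- sample(30:200, 2)
    s <- c(rbinom(1, n[1], runif(1, .1, .9)), rbinom(1, n[2], runif(1, .1, .9)))
    s <- pmax(pmin(s, n - 1), 1) # avoid separation: compare the glm route
    cmp <- compare_groups_logistic(s, n, c("A", "B"))
    fp <- fisher_exact_2x2(s[1], n[1] - s[1], s[2], n[2] - s[2])
    if ((cmp$pairs$adj_p[1] <= 0.05) == (fp <= 0.05)) agree <- agree + 1
  }
  expect_gte(agree, 95)
})

test_that("letter display shares a letter exactly when not significant", {
  set.seed(3)
  for (rep in 1:20) {
    k <- sample(3:6, 1)
    groups <- LETTERS[1:k]
    n <- sample(50:150, k, replace = TRUE)
    s <- rbinom(k, n, runif(k, 0.05, 0.95))
    s <- pmax(pmin(s, n - 1), 1)
    cmp <- compare_groups_logistic(s, n, groups)
    for (i in seq_len(nrow(cmp$pairs))) {
      li <- strsplit(cmp$letters[cmp$pairs$group1[i]], "")[[1]]
      lj <- strsplit(cmp$letters[cmp$pairs$group2[i]], "")[[1]]
      shares <- length(intersect(li, lj)) > 0
      expect_equal(shares, cmp$pairs$adj_p[i] > 0.05)
    }
  }
})

test_that("family pairing and population summaries reproduce order statistics", {
  batches <- data.frame(
    population = rep("P", 4), family = rep(c("f1", "f2"), each = 2),
    treatment = rep(c("control", "ltherm"), 2),
    n_stocked = 100, n_alive_31dpf = c(80, 90, 75, 85),
    n_sexed = c(80, 90, 75, 85), n_males = c(40, 81, 30, 68))
  pairs <- family_pairs(batches)
  expect_equal(pairs$ir[1], inversion_rate(81 / 90, 40 / 80))
  expect_equal(pairs$rsr[2], relative_survival_rate(0.85, 0.75))
  summ <- summarize_population(pairs, batches)
  ctl <- summ$summary[summ$summary$treatment == "control", ]
  expect_equal(ctl$mean, mean(100 * c(40 / 80, 30 / 75)))
  expect_true(all(summ$summary$p25 <= summ$summary$median &
                    summ$summary$median <= summ$summary$p75))
  expect_true(all(nzchar(summ$summary$letters)))
  # single family: mean = median, sd reported as 0
  one <- summarize_population(pairs[1, , drop = FALSE])
  expect_equal(one$summary$mean, one$summary$median)
  expect_equal(one$summary$sd, c(0, 0))
  # quartiles use type-7 linear interpolation
  vals <- c(64, 79, 91, 55)
  fake <- pairs[rep(1, 4), ]; fake$sr_control <- vals / 100
  fake$family <- paste0("f", 1:4)
  s2 <- summarize_population(fake)
  expect_equal(s2$summary$median[s2$summary$treatment == "control"],
               unname(stats::quantile(vals, 0.5, type = 7)))
  # permuting family order leaves all summaries unchanged
  perm <- family_pairs(batches[c(3, 4, 1, 2), ])
  s_perm <- summarize_population(perm, batches)
  expect_equal(s_perm$summary$mean, summ$summary$mean)
  expect_equal(s_perm$summary$sd, summ$summary$sd)
  expect_error(family_pairs(transform(batches, treatment = "hot")),
               "invalid treatment")
})
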