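test_that("CPM normalization follows the library-size formula", {
  m <- matrix(c(10), 1, 1, dimnames = list("g1", "s1"))
  expect_equal(as.vector(cpm(m)), 1e6)
  m2 <- matrix(c(25, 75), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(as.vector(cpm(m2)), c(250000, 750000))
  # logged zero count at libsize 1e6 and prior 0.5
  m3 <- matrix(c(0, 1e6), 2, 1)
  expect_equal(cpm(m3, log = TRUE, prior_count = 0.5)[1, 1],
               log2((0 + 0.5) / (1e6 + 1) * 1e6), tolerance = 1e-12)
  # un-logged columns sum to 1e6
  set.seed(1)
  m4 <- matrix(rpois(60, 40), 10, 6)
  expect_equal(unname(colSums(cpm(m4))), rep(1e6, 6))
  # agrees with the edgeR implementation
  mine <- cpm(m4, log = TRUE, prior_count = 0.5)
  attr(mine, "lib_sizes") <- NULL
  expect_equal(unname(mine),
               unname(edgeR::cpm(m4, log = TRUE, prior.count = 0.5)),
               tolerance = 1e-10)
  expect_error(cpm(cbind(m2, s2 = c(0, 0))), "zero library")
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("gene-wise least squares matches a normal-equations oracle", {
  set.seed(2)
  n <- 8; p <- 3
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  colnames(X) <- c("(Intercept)", "x", "z")
  Y <- matrix(rnorm(5 * n), 5, n)
  fit <- fit_weighted_lm(Y, X)
  for (g in 1:5) {
    beta <- solve(crossprod(X), crossprod(X, Y[g, ]))
    expect_equal(unname(fit$coefficients[g, ]), as.vector(beta),
                 tolerance = 1e-10)
    expect_equal(unname(fit$stdev_unscaled[g, ]),
                 unname(sqrt(diag(solve(crossprod(X))))), tolerance = 1e-10)
  }
  # weighted case vs explicit weighted normal equations
  W <- matrix(runif(5 * n, 0.2, 3), 5, n)
  fw <- fit_weighted_lm(Y, X, W)
  for (g in 1:5) {
    XtW <- t(X * W[g, ])
    beta <- solve(XtW %*% X, XtW %*% Y[g, ])
    expect_equal(unname(fw$coefficients[g, ]), as.vector(beta),
                 tolerance = 1e-10)
  }
  # noiseless data: exact recovery and zero residual sd
  B <- matrix(rnorm(5 * p), 5, p)
  Y0 <- B %*% t(X)
  f0 <- fit_weighted_lm(Y0, X)
  expect_equal(unname(f0$coefficients), unname(B), tolerance = 1e-8)
  expect_equal(f0$sigma, rep(0, 5), tolerance = 1e-8)
  # rank-deficient designs are rejected with the aliased column named
  expect_error(fit_weighted_lm(Y, cbind(X, x2 = X[, 2])), "x2")
})

test_that("precision weights are flat on homoscedastic data and trend-positive", {
  set.seed(3)
  n <- 12
  design <- cbind(1, rep(0:1, 6))
  # homoscedastic across a wide abundance range: sd constant at 0.4
  mu <- rnorm(800, mean = 6, sd = 2)
  lc <- matrix(rnorm(800 * n, mean = mu, sd = 0.4), 800, n)
  attr(lc, "lib_sizes") <- rep(1e6, n)
  w <- estimate_precision_weights(lc, design)
  expect_true(all(is.finite(w$weights) & w$weights > 0))
  # weights nearly constant (relative range within 20%)
  expect_lt(diff(range(w$weights)) / mean(w$weights), 0.2)
  expect_true(all(is.finite(w$trend$y) & w$trend$y > 0))
  # uniformly scaling all library sizes shifts the abundance axis without
  # changing any weight
  lc2 <- lc; attr(lc2, "lib_sizes") <- rep(2e6, n)
  w2 <- estimate_precision_weights(lc2, design)
  expect_equal(w2$weights, w$weights, tolerance = 1e-6)
  # too few genes falls back to unit weights with a warning
  few <- lc[1:10, ]; attr(few, "lib_sizes") <- rep(1e6, n)
  expect_warning(wf <- estimate_precision_weights(few, design), "unit")
  expect_true(all(wf$weights == 1))
})

test_that("variance moderation is a convex combination matching limma", {
  set.seed(4)
  s2 <- rchisq(300, df = 5) / 5 * exp(rnorm(300, 0, 0.6))
  sq <- squeeze_var(s2, 5)
  expect_true(all(sq$var_post >= pmin(s2, sq$var_prior) - 1e-12))
  expect_true(all(sq$var_post <= pmax(s2, sq$var_prior) + 1e-12))
  lf <- limma::squeezeVar(s2, 5)
  expect_equal(sq$var_post, lf$var.post, tolerance = 1e-8)
  expect_equal(sq$df_prior, lf$df.prior, tolerance = 1e-6)
  expect_equal(sq$var_prior, lf$var.prior, tolerance = 1e-8)
  # trigamma inversion is a true inverse
  y <- c(1e-4, 0.01, 0.5, 2, 50)
  expect_equal(trigamma(thermosex:::trigamma_inverse(y)), y,
               tolerance = 1e-6)
  expect_error(squeeze_var(rep(0, 10), 5), "zero")
})

test_that("moderated t reduces to the ordinary t as the prior vanishes", {
  set.seed(6)
  n <- 10
  design <- cbind("(Intercept)" = 1, treatmentltherm = rep(0:1, each = 5))
  Y <- matrix(rnorm(200 * n), 200, n,
              dimnames = list(sprintf("g%03d", 1:200), NULL))
  fit <- fit_weighted_lm(Y, design)
  mod0 <- moderate_and_test(fit, "treatmentltherm", df_prior_override = 0)
  tt <- apply(Y, 1, function(y) unname(t.test(y[6:10], y[1:5],
                                              var.equal = TRUE)$statistic))
  expect_equal(mod0$t, unname(tt), tolerance = 1e-8)
  # identical arms: fold change 0, t = 0, p = 1
  Yc <- Y; Yc[1, ] <- rep(c(1, 2, 3, 1, 4), 2)
  fitc <- fit_weighted_lm(Yc, design)
  modc <- moderate_and_test(fitc, "treatmentltherm")
  expect_equal(modc$logFC[1], 0, tolerance = 1e-12)
  expect_equal(modc$t[1], 0, tolerance = 1e-12)
  expect_equal(modc$p[1], 1, tolerance = 1e-12)
  # direction calls are consistent with the fold-change sign
  mod <- moderate_and_test(fit, "treatmentltherm")
  expect_true(all(mod$adj_p >= mod$p - 1e-15))
  sig <- mod$direction != "none"
  expect_true(all(sign(mod$logFC[sig]) == ifelse(mod$direction[sig] == "up", 1, -1)))
})

test_that("stratum DE pipeline concords with limma-voom on the same data", {
  sim <- small_sim(seed = 12, n_genes = 400)
  ss <- stratum_of(sim)
  counts <- sim$gene_counts[, ss$sample_id]
  keep <- filter_expressed(counts)
  de <- de_stratum(counts, ss)
  v <- limma::voom(counts[keep, ], paired_design(ss))
  lfit <- limma::eBayes(limma::lmFit(v, paired_design(ss)))
  top <- limma::topTable(lfit, coef = "treatmentltherm", number = Inf,
                         sort.by = "none")
  expect_equal(nrow(de), nrow(top))
  expect_gt(cor(de$logFC, top$logFC), 0.99)
  expect_gt(cor(de$t, top$t), 0.98)
})
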