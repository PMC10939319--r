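test_that("majority-vote identifier resolution keeps the most-referenced link", {
  map <- data.frame(source = c("s1", "s2", "s3"),
                    from_id = "A", to_id = c("X", "X", "Y"))
  expect_equal(resolve_ids(map), c(A = "X"))
  # unanimous sources keep the association
  map3 <- data.frame(source = c("s1", "s2", "s3"), from_id = "B", to_id = "Z")
  expect_equal(resolve_ids(map3), c(B = "Z"))
  # 1-1 ties are dropped with a warning
  tie <- data.frame(source = c("s1", "s2"), from_id = "C", to_id = c("X", "Y"))
  expect_warning(res <- resolve_ids(tie), "tied")
  expect_length(res, 0)
  # idempotence: resolving the resolved table returns itself
  big <- data.frame(source = rep(c("s1", "s2", "s3"), each = 4),
                    from_id = rep(sprintf("g%d", 1:4), 3),
                    to_id = c(rep(c("x1", "x2", "x3", "x4"), 2),
                              c("x1", "q", "x3", "x4")))
  res1 <- resolve_ids(big)
  again <- data.frame(source = "resolved", from_id = names(res1),
                      to_id = unname(res1))
  expect_equal(resolve_ids(again), res1)
})

test_that("ortholog augmentation unions native and donor terms per gene", {
  native <- list(T1 = c("g1", "g2"), T2 = "g3")
  donor <- list(T2 = c("H1", "H9"), T3 = "H2")
  omap <- c(g1 = "H1", g4 = "H2")
  out <- augment_by_ortholog(native, omap, donor)
  expect_setequal(out$T2, c("g3", "g1"))  # g1 gains T2 via its ortholog
  expect_setequal(out$T3, "g4")           # no native terms, donor only
  expect_equal(out$T1, native$T1)         # untouched
  # empty donor leaves the annotation unchanged
  expect_equal(augment_by_ortholog(native, omap, list()), native)
  # gene-wise union property on random fixtures
  set.seed(4)
  for (i in 1:20) {
    genes <- sprintf("g%02d", 1:20)
    hums <- sprintf("H%02d", 1:20)
    nat <- lapply(1:5, function(t) sample(genes, sample(1:8, 1)))
    names(nat) <- sprintf("T%d", 1:5)
    don <- lapply(1:5, function(t) sample(hums, sample(1:8, 1)))
    names(don) <- sprintf("T%d", 1:5)
    om <- setNames(sample(hums), genes)
    out <- augment_by_ortholog(nat, om, don)
    for (term in names(out)) {
      want <- union(if (term %in% names(nat)) nat[[term]] else character(),
                    names(om)[om[genes] %in% don[[term]]])
      expect_setequal(out[[term]], want)
    }
  }
})

test_that("hypergeometric enrichment equals the pmf-sum oracle", {
  universe <- sprintf("u%02d", 1:20)
  term <- universe[1:5]
  res <- hypergeom_enrich(universe[1:5], universe, list(T1 = term),
                          min_term_size = 1)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$k, 5)
  expect_equal(res$fold, (5 / 5) / (5 / 20))
  # a term equal to the whole universe is certain: p = 1
  res2 <- hypergeom_enrich(universe[1:5], universe, list(T1 = universe),
                           min_term_size = 1, max_term_size = 100)
  expect_equal(res2$p, 1)
  # oracle comparison: sum of hypergeometric pmf over the upper tail
  set.seed(5)
  pmf_oracle <- function(k, K, n, N) {
    xs <- k:min(K, n)
    sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
  }
  for (i in 1:500) {
    N <- sample(20:200, 1)
    uni <- sprintf("x%03d", 1:N)
    K <- sample(2:min(50, N), 1)
    n <- sample(2:min(50, N), 1)
    term <- sample(uni, K)
    lst <- sample(uni, n)
    res <- hypergeom_enrich(lst, uni, list(T = term), min_term_size = 1)
    k <- length(intersect(term, lst))
    expect_equal(res$p, pmf_oracle(k, K, n, N), tolerance = 1e-10)
  }
  # p is monotone decreasing in the overlap k at fixed N, K, n
  ps <- vapply(0:5, function(k) phyper(k - 1, 5, 15, 5, lower.tail = FALSE), 1)
  expect_true(all(diff(ps) < 0))
  expect_error(hypergeom_enrich(character(), universe, list(T1 = term)),
               "non-empty")
})

test_that("categorized runs split the evidence into the five reporting lists", {
  set.seed(6)
  genes <- sprintf("g%03d", 1:100)
  ev <- data.frame(gene = genes,
                   deg_direction = sample(c("up", "down", "none"), 100, TRUE),
                   logFC = rnorm(100), adj_p = runif(100),
                   dsg = sample(c(TRUE, FALSE), 100, TRUE, prob = c(.1, .9)),
                   corr_sign = sample(c("+", "-", "none"), 100, TRUE))
  ann <- lapply(1:8, function(i) sample(genes, 20))
  names(ann) <- sprintf("T%d", 1:8)
  out <- run_categorized(ev, ann)
  expect_true(all(names(out) %in% c("↑Exp", "↓Exp", "+Corr", "-Corr", "DSG")))
  # per-category results equal a direct call with that list
  direct <- hypergeom_enrich(ev$gene[ev$deg_direction == "up"], genes, ann)
  expect_equal(out[["↑Exp"]][, names(direct)], direct)
  # adjusted p never below raw p
  for (cat in names(out)) {
    expect_true(all(out[[cat]]$adj_p >= out[[cat]]$p - 1e-15))
  }
  # a gene may legitimately sit in both an Exp and a Corr category
  ev2 <- ev; ev2$deg_direction[1] <- "up"; ev2$corr_sign[1] <- "+"
  out2 <- run_categorized(ev2, ann)
  expect_true(all(c("↑Exp", "+Corr") %in% names(out2)))
  # only one category populated: exactly one output
  ev3 <- ev; ev3$deg_direction <- "up"; ev3$corr_sign <- "none"
  ev3$dsg <- FALSE
  expect_equal(names(run_categorized(ev3, ann)), "↑Exp")
})
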