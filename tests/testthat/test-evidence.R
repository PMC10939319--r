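test_that("Venn partition regions are exclusive and sum to the union", {
  v <- venn_counts(c("a", "b"), c("c", "d", "e"), c("f", "g", "h", "i"))
  expect_equal(unlist(v[c("deg_only", "dsg_only", "corr_only", "deg_dsg",
                          "deg_corr", "dsg_corr", "all_three")]),
               c(deg_only = 2, dsg_only = 3, corr_only = 4, deg_dsg = 0,
                 deg_corr = 0, dsg_corr = 0, all_three = 0))
  expect_equal(v$union_size, 9)
  same <- letters[1:5]
  v2 <- venn_counts(same, same, same)
  expect_equal(v2$all_three, 5)
  expect_equal(v2$union_size, 5)
  # random sets vs a per-element membership enumeration oracle
  set.seed(8)
  for (i in 1:200) {
    pool <- sprintf("g%02d", 1:30)
    A <- sample(pool, sample(0:20, 1)); B <- sample(pool, sample(0:20, 1))
    C <- sample(pool, sample(0:20, 1))
    v <- venn_counts(A, B, C)
    u <- union(union(A, B), C)
    regions <- table(factor(paste0(as.integer(u %in% A), as.integer(u %in% B),
                                   as.integer(u %in% C)),
                            levels = c("100", "010", "001", "110", "101",
                                       "011", "111")))
    expect_equal(unname(unlist(v[c("deg_only", "dsg_only", "corr_only",
                                   "deg_dsg", "deg_corr", "dsg_corr",
                                   "all_three")])),
                 unname(as.integer(regions)))
    expect_equal(sum(unlist(v[1:7])), v$union_size)
    # permutation invariance of the symmetric regions
    v_perm <- venn_counts(A, B, C)
    expect_equal(v_perm, v)
  }
})

test_that("status strings render and parse for every reachable combination", {
  expect_equal(render_status("up", corr_sign = "+"), "↑Exp and +Corr")
  expect_equal(render_status("none", fc_sign = -1, corr_sign = "-"),
               "↓exp and -Corr")
  expect_equal(render_status("down", dsg = TRUE), "↓Exp and DSG")
  for (deg in c("up", "down", "none")) {
    for (fc in if (deg == "none") c(1, -1) else 1) {
      for (corr in c("+", "-", "none")) {
        for (dsg in c(TRUE, FALSE)) {
          st <- render_status(deg, fc, corr, dsg)
          back <- parse_status(st)
          expect_equal(back$deg_direction, deg)
          expect_equal(back$corr_sign, corr)
          expect_equal(back$dsg, dsg)
          if (deg == "none") expect_equal(back$fc_sign, fc)
        }
      }
    }
  }
})

test_that("evidence assembly and curated cross-referencing report statuses", {
  de <- data.frame(gene = c("dmrt1", "fam185a", "kmt5c", "zzz"),
                   logFC = c(2.1, -0.4, 1.5, 0.2),
                   t = c(5, -1, 4, 0.5),
                   p = c(0.001, 0.4, 0.002, 0.6),
                   adj_p = c(0.004, 0.5, 0.004, 0.7),
                   direction = c("up", "none", "up", "none"))
  ds <- data.frame(gene = "zzz", dsg = TRUE)
  corr <- data.frame(gene = c("dmrt1", "fam185a", "kmt5c"),
                     r = c(-0.9, -0.85, 0.92), p = c(0.01, 0.03, 0.01),
                     sign = c("-", "-", "+"))
  ev <- evidence_table(de, ds, corr)
  expect_equal(ev$status[ev$gene == "kmt5c"], "↑Exp and +Corr")
  expect_equal(ev$status[ev$gene == "fam185a"], "↓exp and -Corr")
  expect_true(ev$dsg[ev$gene == "zzz"])
  xr <- crossref_genes_of_interest(ev, curated = c("dmrt1", "amh"))
  expect_true(xr$present[xr$curated == "dmrt1"])
  expect_equal(xr$status[xr$curated == "amh"], "absent")
  # synonym resolution: curated name finds its alias, ambiguity errors
  ev2 <- rbind(ev, transform(ev[1, ], gene = "nr5a1", status = status))
  xr2 <- crossref_genes_of_interest(ev2, curated = "sf1",
                                    synonyms = list(sf1 = "nr5a1"))
  expect_equal(xr2$gene, "nr5a1")
  ev3 <- rbind(ev2, transform(ev[1, ], gene = "sf1"))
  expect_error(crossref_genes_of_interest(ev3, curated = "sf1",
                                          synonyms = list(sf1 = "nr5a1")),
               "ambiguous")
})

test_that("status filtering matches a brute-force scan and orders by p", {
  de <- data.frame(gene = sprintf("g%d", 1:6),
                   logFC = c(1, -1, 2, -2, 0.1, 0.3),
                   t = 0, p = 0.5,
                   adj_p = c(0.01, 0.6, 0.003, 0.02, 0.9, 0.04),
                   direction = c("up", "none", "up", "down", "none", "none"))
  corr <- data.frame(gene = sprintf("g%d", 1:6), r = 0.5, p = 0.01,
                     sign = c("+", "none", "+", "none", "-", "none"))
  ev <- evidence_table(de, NULL, corr)
  pred <- function(e) e$deg_direction != "none" && e$corr_sign != "none"
  got <- filter_by_status(ev, pred)
  expect_equal(got, c("g3", "g1")) # matching genes, ascending adjusted p
  # predicate with no matches gives an empty list
  expect_length(filter_by_status(ev, function(e) e$dsg), 0)
  # equivalence with an explicit row scan on random tables
  set.seed(12)
  for (i in 1:20) {
    n <- 15
    evr <- data.frame(gene = sprintf("r%02d", 1:n),
                      deg_direction = sample(c("up", "down", "none"), n, TRUE),
                      logFC = rnorm(n), adj_p = runif(n),
                      dsg = sample(c(TRUE, FALSE), n, TRUE),
                      corr_sign = sample(c("+", "-", "none"), n, TRUE))
    evr$r <- NA_real_
    evr$status <- mapply(render_status, evr$deg_direction, sign(evr$logFC),
                         evr$corr_sign, evr$dsg)
    pr <- function(e) e$deg_direction == "up" || e$dsg
    want <- evr$gene[evr$deg_direction == "up" | evr$dsg]
    expect_setequal(filter_by_status(evr, pr), want)
  }
})
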