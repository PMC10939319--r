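# small simulated fixtures shared across test files

small_sim <- function(seed = 1, n_genes = 300, ...) {
  simulate_counts(sim_config(n_genes = n_genes, seed = seed, ...))
}

stratum_of <- function(sim, tissue = "gonad", stage = 40) {
  sh <- sim$sample_sheet
  sh[sh$tissue == tissue & sh$stage_dpf == stage, , drop = FALSE]
}

# independent enumeration oracle for the two-sided Fisher test on a 2x2
# table: sum of hypergeometric probabilities over all admissible tables
# whose probability does not exceed the observed one
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k))
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force BH step-up definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
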