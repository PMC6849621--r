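# Shared fixtures and small independent oracles used across tests.

# Left-filled subset-chain matrix with the given row richnesses.
subset_chain <- function(m, n, rich) {
  rich <- sort(rich, decreasing = TRUE)
  stopifnot(length(rich) == m, all(rich >= 0), all(rich <= n))
  t(vapply(rich, function(r) c(rep(1L, r), rep(0L, n - r)), integer(n)))
}

# Canonical three-role community as plain numbers, independent of the
# package constructors, for hand-evaluated oracles.
ref_params <- function(h = 1) {
  list(c = c(0.20, 1.60, 0.18), d = c(0.1, 0.1, 0.1), h = rep(h, 3),
       alpha = rbind(c(1.00, 0.01, 0.00),
                     c(1.50, 1.00, 0.00),
                     c(0.50, 0.30, 1.00)))
}

# Direct scalar evaluation of the rate equation, written as loops so it
# stays independent of the vectorised implementation.
rate_oracle <- function(n, pars) {
  S <- length(n)
  out <- numeric(S)
  for (i in seq_len(S)) {
    comp <- 0
    for (j in seq_len(S)) comp <- comp + pars$alpha[i, j] * n[j]
    out[i] <- (pars$c[i] * (pars$h[i] - comp) - pars$d[i]) * n[i]
  }
  out
}

# Pearson r and two-sided p computed from first principles.
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

# A quick anti-/in-phase synthetic core plus its paired diff series.
phase_core_correlation <- function(phase, seed, n_sections = 90) {
  core <- generate_core(scenario_config(phase = phase, seed = seed),
                        n_sections)
  paired <- pair_series(disorder_series(core), core_diversity(core))
  sc <- sequential_correlations(first_differences(paired))
  sc[nrow(sc), ]
}
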