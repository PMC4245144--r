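# Independent oracles used across test files.

# Riemann-sum integral on the same grid as the trapezoid (piecewise-linear
# interpolation integrated segment by segment with midpoint evaluation).
riemann_oracle <- function(days, values, n_sub = 1000) {
  total <- 0
  for (i in seq_len(length(days) - 1)) {
    h <- (days[i + 1] - days[i]) / n_sub
    x <- days[i] + (seq_len(n_sub) - 0.5) * h
    y <- values[i] + (values[i + 1] - values[i]) *
      (x - days[i]) / (days[i + 1] - days[i])
    total <- total + sum(y) * h
  }
  total
}

# Tiny hand-built distance sample: one row per paired observation.
make_sample <- function(pd, nd = rep(NA_real_, length(pd)), limit = 0.15) {
  distance_sample(pd, is.na(pd), nd,
                  ifelse(is.na(pd), NA, is.na(nd)),
                  field_limit = limit)
}

# Mean corrected-density estimate over CSR replicates at a given intensity.
csr_estimates <- function(lambda, n_reps, n_transects = 12, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n_reps), function(i) {
    pat <- simulate_poisson_pattern(lambda)
    smp <- sample_transects(pat, n_transects = n_transects)
    R <- select_truncation_radius(smp$point_distance_m)
    dp <- as.numeric(estimate_point_density(smp, R))
    dn <- as.numeric(estimate_neighbor_density(smp, R))
    c(dp = dp, dn = dn, dc = corrected_point_density(dp, dn))
  }, numeric(3))
}
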