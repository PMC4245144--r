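test_that("truncation radius is the linear-interpolation quantile", {
  # degenerate: all distances equal
  expect_equal(select_truncation_radius(rep(0.10, 8), 0.30), 0.10)

  # ten evenly spaced distances, exclude 30%: the type-7 quantile
  d <- seq(0.01, 0.10, by = 0.01)
  R <- select_truncation_radius(d, 0.30)
  # brute-force oracle: order statistics x_(7) + 0.3 (x_(8) - x_(7))
  expect_equal(R, 0.07 + 0.3 * 0.01)
  expect_equal(sum(d > R), 3)  # exactly 3 of 10 excluded

  # exclude nothing -> the maximum
  expect_equal(select_truncation_radius(d, 0), 0.10)

  expect_error(select_truncation_radius(c(NA_real_, NA_real_)), "censored")
  expect_error(select_truncation_radius(d, 1), "exclude_fraction")
})

test_that("point density estimator matches closed forms and flags emptiness", {
  # one point, one flower at distance d, R >= d: 1 / (pi d^2)
  s <- make_sample(0.05)
  expect_equal(as.numeric(estimate_point_density(s, 0.1)), 1 / (pi * 0.05^2))

  # all censored -> 0, flagged, with a warning
  s0 <- make_sample(c(NA_real_, NA_real_))
  expect_warning(z <- estimate_point_density(s0, 0.1), "0")
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "flagged"))

  # censored points contribute searched area pi R^2
  s2 <- make_sample(c(0.05, NA))
  expect_equal(as.numeric(estimate_point_density(s2, 0.1)),
               1 / (pi * (0.05^2 + 0.1^2)))

  # truncation: distances beyond R count as censored at R
  s3 <- make_sample(c(0.05, 0.12))
  expect_equal(as.numeric(estimate_point_density(s3, 0.1)),
               1 / (pi * (0.05^2 + 0.1^2)))

  expect_error(estimate_point_density(s, 0.2), "field")
})

test_that("neighbour estimator divides by the area actually searched", {
  # single pair: flower found at d, neighbour at r. The searched area is
  # the neighbour disc minus the lens shared with the (empty) point disc.
  d <- 0.001  # point almost on the flower: lens -> 0, estimate -> 1/(pi r^2)
  r <- 0.06
  s <- make_sample(d, r)
  expect_equal(as.numeric(estimate_neighbor_density(s, 0.1)),
               1 / (pi * r^2), tolerance = 0.02)

  # numeric-oracle check of the lens geometry at comparable radii:
  # Monte-Carlo area of B(f, r) \ B(p, d) with f = (d, 0), p = (0, 0)
  d <- 0.05; r <- 0.07
  set.seed(99)
  x <- runif(4e5, d - r, d + r); y <- runif(4e5, -r, r)
  inside <- (x - d)^2 + y^2 <= r^2 & (x^2 + y^2 > d^2)
  mc_area <- mean(inside) * (2 * r)^2
  s2 <- make_sample(d, r)
  expect_equal(as.numeric(estimate_neighbor_density(s2, 0.1)),
               1 / mc_area, tolerance = 0.01)

  # censored neighbour search contributes the full truncated search area
  s3 <- make_sample(c(0.001, 0.001), c(0.06, NA))
  expect_equal(as.numeric(estimate_neighbor_density(s3, 0.1)),
               1 / (pi * 0.06^2 + pi * 0.1^2), tolerance = 0.02)

  expect_warning(z <- estimate_neighbor_density(make_sample(0.05, NA), 0.1))
  expect_true(attr(z, "flagged"))
})

test_that("corrected density is the geometric mean and sits between inputs", {
  expect_equal(corrected_point_density(150, 150), 150)
  expect_equal(corrected_point_density(100, 400), 200)
  expect_true(corrected_point_density(100, 400) > 100 &&
                corrected_point_density(100, 400) < 400)
  expect_error(corrected_point_density(-1, 2), "non-negative")
})

test_that("estimators are scale-equivariant: distances x c -> density / c^2", {
  set.seed(8)
  pd <- runif(30, 0.01, 0.12)
  nd <- runif(30, 0.01, 0.12)
  c_scale <- 0.5
  s1 <- make_sample(pd, nd, limit = 0.15)
  s2 <- make_sample(pd * c_scale, nd * c_scale, limit = 0.15 * c_scale)
  R1 <- select_truncation_radius(pd)
  expect_equal(select_truncation_radius(pd * c_scale), R1 * c_scale)
  expect_equal(as.numeric(estimate_point_density(s2, R1 * c_scale)),
               as.numeric(estimate_point_density(s1, R1)) / c_scale^2)
  expect_equal(as.numeric(estimate_neighbor_density(s2, R1 * c_scale)),
               as.numeric(estimate_neighbor_density(s1, R1)) / c_scale^2)
})

test_that("standard error back-computation from confidence limits", {
  # arithmetic: width 4, t = 2 -> SE 1 (level chosen so qt gives exactly 2
  # is awkward; check the formula directly against qt)
  expect_equal(se_from_ci(0, 4, n_points = 10, level = 0.95),
               4 / (2 * qt(0.975, 9)))
  expect_equal(se_from_ci(5, 5, n_points = 72), 0)
  # independent oracle: published t table gives t(0.975, 71) = 1.9939
  expect_equal(se_from_ci(0, 10, n_points = 72, level = 0.95),
               10 / (2 * 1.9939), tolerance = 1e-4)
  expect_error(se_from_ci(2, 1, 10), "ci_high")
})

test_that("bootstrap interval is reproducible, degenerate-safe, and brackets", {
  # identical observations -> zero-width interval
  s <- make_sample(rep(0.05, 20), rep(0.04, 20))
  ci <- bootstrap_ci(s, n_boot = 200, seed = 1)
  expect_equal(ci[["ci_low"]], ci[["ci_high"]])

  # fixed seed -> identical interval
  pat <- simulate_poisson_pattern(150, seed = 2)
  smp <- sample_transects(pat, n_transects = 12, seed = 3)
  expect_identical(bootstrap_ci(smp, n_boot = 200, seed = 4),
                   bootstrap_ci(smp, n_boot = 200, seed = 4))

  # interval contains the point estimate
  est <- estimate_density(smp, n_boot = 400, seed = 5)
  expect_gte(est$per_ha, est$ci_low)
  expect_lte(est$per_ha, est$ci_high)

  # all censored -> estimation error
  expect_error(bootstrap_ci(make_sample(c(NA_real_, NA_real_)), n_boot = 100),
               "censored")
})

test_that("per-hectare conversion is exact and the wrapper is consistent", {
  pat <- simulate_poisson_pattern(200, seed = 10)
  smp <- sample_transects(pat, n_transects = 12, seed = 11)
  est <- estimate_density(smp, n_boot = 200, seed = 12)
  expect_identical(est$per_ha, est$d_corrected * 1e4)
  expect_equal(est$d_corrected,
               corrected_point_density(est$d_point, est$d_neighbor))
  expect_equal(est$n_points, 72)
})

test_that("estimators recover a known CSR intensity", {
  # quick consistency check at one intensity; the full multi-intensity
  # validation lives in the acceptance suite
  r <- csr_estimates(200, n_reps = 120, seed = 13)
  expect_lt(abs(mean(r["dc", ]) / 200 - 1), 0.05)
  expect_lt(abs(mean(r["dp", ]) / 200 - 1), 0.05)
  expect_lt(abs(mean(r["dn", ]) / 200 - 1), 0.06)
})
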