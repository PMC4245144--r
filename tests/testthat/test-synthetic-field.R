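test_that("Poisson pattern has the right intensity, support, and determinism", {
  # zero intensity -> empty pattern
  expect_equal(nrow(simulate_poisson_pattern(0, seed = 1)$coords), 0)

  # counts match Poisson(lambda * A) moments over many seeds
  lambda <- 100
  area <- 3.1 * 12.2
  counts <- vapply(1:150, function(s)
    nrow(simulate_poisson_pattern(lambda, seed = s)$coords), numeric(1))
  mu <- lambda * area
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / length(counts)))
  # Poisson: variance ~ mean (Monte-Carlo error on var is ~ mu*sqrt(2/(n-1)))
  expect_lt(abs(var(counts) - mu), 4 * mu * sqrt(2 / (length(counts) - 1)))

  # coordinates inside plot
  pat <- simulate_poisson_pattern(50, seed = 7)
  expect_true(all(pat$coords[, 1] >= 0 & pat$coords[, 1] <= 3.1))
  expect_true(all(pat$coords[, 2] >= 0 & pat$coords[, 2] <= 12.2))

  # bit-reproducible under a fixed seed
  a <- simulate_poisson_pattern(1, plot_width = 1, plot_length = 1, seed = 42)
  b <- simulate_poisson_pattern(1, plot_width = 1, plot_length = 1, seed = 42)
  expect_identical(a$coords, b$coords)

  expect_error(simulate_poisson_pattern(-1), "non-negative")
  expect_error(simulate_poisson_pattern(1, plot_width = 0), "positive")
})

test_that("Thomas pattern is overdispersed when tight, CSR-like when loose", {
  # no offspring -> empty
  expect_equal(nrow(simulate_thomas_pattern(0.5, 0, 0.05, seed = 1)$coords), 0)

  # tight clusters: quadrat variance/mean ratio well above 1
  set.seed(11)
  vm <- vapply(1:40, function(i) {
    q <- quadrat_counts(simulate_thomas_pattern(0.5, 20, 0.05))
    var(q) / mean(q)
  }, numeric(1))
  expect_gt(mean(vm), 1.5)

  # cluster_sd of the order of the plot: nearest-neighbour mean distance
  # within 5% of the CSR closed form 1/(2 sqrt(lambda))
  set.seed(12)
  nn <- unlist(lapply(1:40, function(i) {
    pat <- simulate_thomas_pattern(0.5, 100, 15, plot_width = 10,
                                   plot_length = 10)
    xy <- pat$coords
    # realized intensity differs from nominal because loose clusters leak
    # most offspring outside the plot; compare against the realized one
    lam <- nrow(xy) / pattern_area(pat)
    d <- as.matrix(dist(xy))
    diag(d) <- Inf
    # interior flowers only, to dodge edge effects
    interior <- xy[, 1] > 1 & xy[, 1] < 9 & xy[, 2] > 1 & xy[, 2] < 9
    apply(d[interior, , drop = FALSE], 1, min) * 2 * sqrt(lam)
  }))
  expect_lt(abs(mean(nn) - 1), 0.05)

  # recorded generating density is parent_density * mean_offspring
  expect_equal(simulate_thomas_pattern(0.5, 20, 0.05, seed = 3)$true_density, 10)
  expect_error(simulate_thomas_pattern(-1, 5, 0.1), "non-negative")
})

test_that("transect sampling censors correctly and respects geometry", {
  empty <- flower_pattern(matrix(numeric(0), ncol = 2))
  smp <- sample_transects(empty, seed = 1)
  expect_true(all(smp$point_censored))
  expect_true(all(is.na(smp$point_distance_m)))

  # a transect longer than both plot dimensions cannot be placed
  tiny <- flower_pattern(matrix(c(0.5, 0.5), ncol = 2), 1, 1)
  expect_error(sample_transects(tiny, point_spacing = 0.5,
                                points_per_transect = 6), "longer")

  # single flower: if found, its neighbour search must censor
  one <- flower_pattern(matrix(c(1.5, 6), ncol = 2))
  set.seed(2)
  for (i in 1:20) {
    s <- sample_transects(one, n_transects = 10)
    found <- !s$point_censored
    expect_true(all(is.na(s$neighbor_distance_m[found])))
    expect_true(all(s$neighbor_censored[found]))
  }

  # censoring probability under CSR ~ exp(-lambda * pi * r^2)
  lambda <- 30
  p_cens <- exp(-lambda * pi * 0.15^2)
  set.seed(3)
  cens <- unlist(lapply(1:30, function(i) {
    sample_transects(simulate_poisson_pattern(lambda),
                     n_transects = 6)$point_censored
  }))
  n <- length(cens)
  expect_lt(abs(mean(cens) - p_cens),
            3 * sqrt(p_cens * (1 - p_cens) / n) + 0.01)

  # dense pattern: essentially no censoring
  dense <- sample_transects(simulate_poisson_pattern(500, seed = 4),
                            n_transects = 12, seed = 5)
  expect_lt(mean(dense$point_censored), 0.05)

  # reproducibility
  pat <- simulate_poisson_pattern(100, seed = 6)
  expect_identical(sample_transects(pat, seed = 9),
                   sample_transects(pat, seed = 9))
})

test_that("simulated phenology hits its stated peak, span, and honey-bee share", {
  p <- phenology_params(peak_cover = 40, peak_day_offset = 17,
                        anthesis_duration = 55)
  s <- simulate_phenology(p, noise_cv = 0, seed = 1)
  expect_equal(max(s$cover), 40)
  expect_equal(s$days_since_first_flower[which.max(s$cover)], 17)
  expect_equal(diff(range(s$day)), 55)
  expect_true(all(s$cover >= 0 & s$cover <= 100))

  # noise-free visitation is exact and split at the stated share
  # (anthesis endpoints have zero rate, so the ratio is defined elsewhere)
  act <- s$total_rate > 0
  expect_equal(s$honey_bee[act] / s$total_rate[act],
               rep(0.5, sum(act)), tolerance = 1e-12)

  # with count noise the season honey-bee share stays within binomial error
  s2 <- simulate_phenology(p, noise_cv = 0.15, seed = 22)
  eff <- s2$observers[1] * s2$minutes[1]
  n_insects <- sum(s2$total_rate) * eff
  hb <- honeybee_fraction(s2)$season
  expect_lt(abs(hb - 0.5), 3 * sqrt(0.25 / n_insects) + 0.02)

  expect_identical(simulate_phenology(p, seed = 5),
                   simulate_phenology(p, seed = 5))
  expect_error(phenology_params(peak_cover = 120), "peak_cover")
  expect_error(phenology_params(honeybee_share = 2), "honeybee_share")
})

test_that("nectar generator round-trips its interval means", {
  # zero noise: recovered means equal the targets exactly
  rec <- simulate_nectar_records(10, c(170, 295, 170), brix_mean = 34,
                                 noise_cv = 0, seed = 1)
  m <- nectar_interval_means(rec)
  expect_equal(unname(as.numeric(m)), c(170, 295, 170), tolerance = 1e-10)
  expect_equal(daily_flower_sucrose(as.numeric(m)), 635, tolerance = 1e-9)

  # zero Brix: no sugar can be carried, all records imply zero sucrose
  rec0 <- simulate_nectar_records(5, c(100, 100, 100), brix_mean = 0,
                                  noise_cv = 0.2, seed = 2)
  expect_true(all(nectar_interval_means(rec0) == 0))

  # noisy means are unbiased: average over many flowers near targets
  rec2 <- simulate_nectar_records(200, c(170, 295, 170), noise_cv = 0.2,
                                  seed = 3)
  m2 <- as.numeric(nectar_interval_means(rec2))
  expect_equal(m2, c(170, 295, 170), tolerance = 0.05)

  expect_error(simulate_nectar_records(5, c(1, 2)), "three")
  expect_error(simulate_nectar_records(5, c(1, 2, 3), brix_mean = 99), "brix")
})
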