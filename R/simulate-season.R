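#' Phenology and visitation parameters for a simulated season
#'
#' Bundles the season-shape parameters the simulator needs. Defaults emulate
#' an early-sown indeterminate oilseed season in the upper Midwest: first
#' flower about 45 d after sowing, 55 d of anthesis, flower cover peaking
#' near 40% two to three weeks after first flower, open-flower density
#' peaking around 3 x 10^7 ha^-1, total pollinator visitation peaking near
#' 35 insects min^-1 observer^-1 with honey bees making up half of visitors.
#'
#' @param days_to_first_flower days from sowing to first open flower.
#' @param anthesis_duration days from first flower to harvest.
#' @param peak_cover maximum percent flower ground cover (0-100).
#' @param peak_day_offset days from first flower to the cover peak.
#' @param peak_density maximum open-flower density, flowers ha^-1.
#' @param honeybee_share expected fraction of visitors that are honey bees.
#' @param peak_visitation maximum total visitation rate, insects min^-1
#'   observer^-1.
#' @param sowing_doy sowing date as day of year (default 135, mid-May).
#' @return A list of class `phenology_params`.
#' @export
phenology_params <- function(days_to_first_flower = 45, anthesis_duration = 55,
                             peak_cover = 40, peak_day_offset = 17,
                             peak_density = 3e7, honeybee_share = 0.5,
                             peak_visitation = 35, sowing_doy = 135) {
  if (peak_cover < 0 || peak_cover > 100) {
    stop("peak_cover must be in [0, 100]", call. = FALSE)
  }
  if (honeybee_share < 0 || honeybee_share > 1) {
    stop("honeybee_share must be in [0, 1]", call. = FALSE)
  }
  if (days_to_first_flower <= 0 || anthesis_duration <= 0 ||
      peak_day_offset <= 0 || peak_day_offset >= anthesis_duration) {
    stop("durations must be positive and the peak must fall inside anthesis",
         call. = FALSE)
  }
  if (peak_density < 0 || peak_visitation < 0) {
    stop("peak rates must be non-negative", call. = FALSE)
  }
  structure(list(days_to_first_flower = days_to_first_flower,
                 anthesis_duration = anthesis_duration,
                 peak_cover = peak_cover, peak_day_offset = peak_day_offset,
                 peak_density = peak_density, honeybee_share = honeybee_share,
                 peak_visitation = peak_visitation, sowing_doy = sowing_doy),
            class = "phenology_params")
}

#' Insect categories recorded during visitation counts
#' @return Character vector of the six count categories.
#' @export
insect_categories <- function() {
  c("honey_bee", "bumble_bee", "other_bee", "fly", "butterfly", "other_insect")
}

# Unimodal season shape on [0, duration], scaled so the curve equals 1 at the
# peak day. Beta-density family: mode at offset/duration, zero at both ends.
season_shape <- function(t, duration, peak_offset, concentration = 4) {
  m <- peak_offset / duration
  a <- 1 + concentration * m
  b <- 1 + concentration * (1 - m)
  stats::dbeta(t / duration, a, b) / stats::dbeta(m, a, b)
}

#' Simulate a flowering season
#'
#' Builds day-by-day percent flower cover, open-flower density, and
#' per-category pollinator visitation rates over the anthesis window
#' (first flower to harvest). All three curves share a unimodal scaled-beta
#' shape that is zero at both ends of anthesis and reaches its stated peak
#' at `peak_day_offset`. Cover and density get multiplicative lognormal
#' observation noise of coefficient of variation `noise_cv`; visitation is
#' observed as Poisson insect counts over `observers * minutes` of
#' observation, split across the six categories with honey bees at
#' `honeybee_share` in expectation. With `noise_cv = 0` every curve is
#' returned noise-free and exact (no count sampling either), which is the
#' configuration used for arithmetic round-trip checks.
#'
#' @param params a [phenology_params()].
#' @param sampling_interval days between observations (>= 1).
#' @param noise_cv coefficient of variation of the lognormal observation
#'   noise (0 disables all noise).
#' @param observers,minutes observation effort behind each visitation count.
#' @param treatment,year labels carried into the series.
#' @param seed optional integer seed.
#' @return A data.frame of class `season_series` with columns `day` (day of
#'   year), `days_since_first_flower`, `cover`, `flower_density_ha`, one
#'   column per [insect_categories()] (rates, insects min^-1 observer^-1),
#'   `total_rate`, `observers`, `minutes`, `treatment`, `year`.
#' @export
simulate_phenology <- function(params, sampling_interval = 1, noise_cv = 0.15,
                               observers = 2, minutes = 1.5,
                               treatment = "early", year = NA_integer_,
                               seed = NULL) {
  stopifnot(inherits(params, "phenology_params"))
  if (sampling_interval < 1) {
    stop("sampling_interval must be at least 1 day", call. = FALSE)
  }
  local_seed(seed)
  D <- params$anthesis_duration
  t <- seq(0, D, by = sampling_interval)
  if (t[length(t)] < D) t <- c(t, D)  # always observe through harvest
  shape <- season_shape(t, D, params$peak_day_offset)
  first_doy <- params$sowing_doy + params$days_to_first_flower

  cover <- params$peak_cover * shape
  dens <- params$peak_density * shape
  vis_total <- params$peak_visitation * shape
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    cover <- pmin(100, cover * stats::rlnorm(length(t), -sdlog^2 / 2, sdlog))
    dens <- dens * stats::rlnorm(length(t), -sdlog^2 / 2, sdlog)
  }

  cats <- insect_categories()
  share <- c(params$honeybee_share,
             rep((1 - params$honeybee_share) / (length(cats) - 1),
                 length(cats) - 1))
  effort <- observers * minutes
  rates <- matrix(0, nrow = length(t), ncol = length(cats),
                  dimnames = list(NULL, cats))
  for (i in seq_along(t)) {
    expected <- vis_total[i] * share
    if (noise_cv > 0) {
      counts <- stats::rpois(length(cats), expected * effort)
      rates[i, ] <- counts / effort
    } else {
      rates[i, ] <- expected
    }
  }

  out <- data.frame(day = first_doy + t, days_since_first_flower = t,
                    cover = cover, flower_density_ha = dens)
  out <- cbind(out, as.data.frame(rates))
  out$total_rate <- rowSums(rates)
  out$observers <- observers
  out$minutes <- minutes
  out$treatment <- treatment
  out$year <- year
  class(out) <- c("season_series", "data.frame")
  out
}

#' Simulate microcapillary nectar records
#'
#' Generates standing-crop nectar measurements for the three 2-h secretion
#' intervals of the daily protocol (0900-1100, 1200-1400, 1500-1700 h). Each
#' flower x interval record carries the capillary size used, the measured
#' nectar column length, and the refractometer Brix reading; the implied
#' sucrose mass (via [nectar_volume()] and [sucrose_mass()]) equals the
#' interval's target mean in expectation, with mean-one lognormal noise of
#' coefficient of variation `noise_cv`. Defaults sum to a daily per-flower
#' production of 635 ug with the midday interval peaking.
#'
#' With `brix_mean = 0` the nectar carries no sugar, so records are emitted
#' with empty columns and every implied sucrose mass is zero; the
#' mean-recovery contract applies only for `brix_mean > 0`.
#'
#' @param n_flowers flowers sampled per interval and date.
#' @param interval_means target mean sucrose mass per flower per 2 h, ug,
#'   one value per interval.
#' @param brix_mean refractometer reading assigned to the records, percent
#'   sucrose (0-85).
#' @param noise_cv coefficient of variation of the per-record lognormal
#'   noise on sucrose mass (0 = exact means).
#' @param dates vector of sampling-date labels (default two dates, the
#'   protocol's replication).
#' @param capillary_length_mm physical capillary length, mm.
#' @param seed optional integer seed.
#' @return data.frame with columns `flower_id`, `date`, `interval`,
#'   `capillary_volume_ul`, `capillary_length_mm`, `column_length_mm`,
#'   `brix`.
#' @export
simulate_nectar_records <- function(n_flowers = 10,
                                    interval_means = c(170, 295, 170),
                                    brix_mean = 34, noise_cv = 0.2,
                                    dates = c("day1", "day2"),
                                    capillary_length_mm = 64, seed = NULL) {
  if (length(interval_means) != 3 || any(interval_means < 0)) {
    stop("interval_means must be three non-negative values", call. = FALSE)
  }
  if (brix_mean < 0 || brix_mean > 85) {
    stop("brix_mean must be in [0, 85]", call. = FALSE)
  }
  local_seed(seed)
  intervals <- c("0900-1100", "1200-1400", "1500-1700")
  grid <- expand.grid(flower = seq_len(n_flowers), interval = seq_along(intervals),
                      date = dates, stringsAsFactors = FALSE)
  target <- interval_means[grid$interval]
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    target <- target * stats::rlnorm(nrow(grid), -sdlog^2 / 2, sdlog)
  }
  if (brix_mean > 0) {
    conc <- brix_to_mg_per_ul(brix_mean)       # mg sucrose per uL nectar
    volume <- target / (1000 * conc)           # uL
  } else {
    volume <- rep(0, nrow(grid))
  }
  if (any(volume > 10)) {
    stop("implied nectar volume exceeds the largest (10 uL) capillary",
         call. = FALSE)
  }
  cap <- vapply(volume, function(v) c(1, 5, 10)[which(v <= c(1, 5, 10))[1]],
                numeric(1))
  data.frame(
    flower_id = sprintf("%s_i%d_f%02d", grid$date, grid$interval, grid$flower),
    date = grid$date,
    interval = intervals[grid$interval],
    capillary_volume_ul = cap,
    capillary_length_mm = capillary_length_mm,
    column_length_mm = volume / cap * capillary_length_mm,
    brix = brix_mean
  )
}
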