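#' Area under an observed time series
#'
#' Trapezoidal integral of a sampled curve over the observed window only —
#' no extrapolation beyond the first or last observation. This is the
#' integral behind all season totals: flower coverage time (%t) from percent
#' cover, pollinator visitation time (pvt) from visitation rates, and the
#' season flower sum from daily flower density.
#'
#' @param days numeric vector of observation days, strictly increasing.
#' @param values numeric vector of the same length.
#' @return The integral in `value x day` units.
#' @examples
#' integrate_series(0:10, rep(10, 11))  # 100 percent-days
#' @export
integrate_series <- function(days, values) {
  if (length(days) < 2 || length(values) != length(days)) {
    stop("need at least two observations with matching days", call. = FALSE)
  }
  if (any(diff(days) <= 0)) {
    stop("days must be strictly increasing with no duplicates", call. = FALSE)
  }
  if (anyNA(days) || anyNA(values)) {
    stop("days and values must not contain NA", call. = FALSE)
  }
  pracma::trapz(days, values)
}

#' Per-observer per-minute visitation rates
#'
#' Normalises raw insect counts by observation effort: each category count
#' is divided by `observers * minutes`, giving insects observed by one
#' observer in one minute.
#'
#' @param counts numeric vector of insect counts (optionally named by
#'   category).
#' @param observers number of observers (>= 1).
#' @param minutes duration of the observation period (> 0).
#' @return Numeric vector of rates, same names as `counts`.
#' @export
visitation_rate <- function(counts, observers, minutes) {
  if (observers < 1) stop("observers must be at least 1", call. = FALSE)
  if (!is.finite(minutes) || minutes <= 0) {
    stop("minutes must be positive", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  counts / (observers * minutes)
}

#' Season flower sum per hectare
#'
#' Trapezoidal integral of the daily open-flower density curve across
#' anthesis, giving the cumulative number of flowers produced per hectare
#' over the season.
#'
#' @param days observation days (strictly increasing).
#' @param flower_density open-flower density, flowers ha^-1, per day.
#' @return Flowers ha^-1 season^-1.
#' @export
season_flower_sum <- function(days, flower_density) {
  if (any(flower_density < 0, na.rm = TRUE)) {
    stop("flower density must be non-negative", call. = FALSE)
  }
  integrate_series(days, flower_density)
}

#' Visitation intensity (pvt per %t)
#'
#' Ratio of pollinator visitation time to flower coverage time. A larger
#' value means more insects per unit of flower area on offer.
#'
#' @param pvt pollinator visitation time (rate-days).
#' @param coverage_time flower coverage time (percent-days), > 0.
#' @return The ratio, full precision (report rounded to 2 decimals).
#' @export
visitation_intensity <- function(pvt, coverage_time) {
  if (any(coverage_time <= 0)) {
    stop("coverage_time must be positive; intensity undefined at zero cover",
         call. = FALSE)
  }
  if (any(pvt < 0)) stop("pvt must be non-negative", call. = FALSE)
  pvt / coverage_time
}

#' One quantity as a percentage of another
#'
#' `100 * value_a / value_b`, rounded to whole percent for reporting by
#' default. Used for treatment contrasts such as late-sown coverage time as
#' a percentage of early-sown, where the printed contrast is the ratio
#' reading (late/early), not the increment.
#'
#' @param value_a,value_b numerator and denominator; `value_b > 0`.
#' @param rounded round to integer percent (default TRUE).
#' @return Percent.
#' @export
relative_percent <- function(value_a, value_b, rounded = TRUE) {
  if (any(value_b <= 0)) stop("denominator must be positive", call. = FALSE)
  p <- 100 * value_a / value_b
  if (rounded) round(p) else p
}

#' Honey-bee share of pollinator visitation
#'
#' Per-observation honey-bee fraction of the total visitation rate, and the
#' season aggregate computed as the ratio of the honey-bee and total
#' visitation integrals. Days with zero total visitation have an undefined
#' daily fraction (`NA`) and contribute nothing to either integral.
#'
#' @param series a `season_series` from [simulate_phenology()], or any
#'   data.frame with a `day` column and the [insect_categories()] rate
#'   columns.
#' @return List with `daily` (numeric vector, `NA` where total is zero) and
#'   `season` (scalar fraction).
#' @export
honeybee_fraction <- function(series) {
  cats <- insect_categories()
  stopifnot(all(c("day", cats) %in% names(series)))
  total <- rowSums(series[cats])
  hb <- series$honey_bee
  daily <- ifelse(total > 0, hb / total, NA_real_)
  season <- if (all(total == 0)) {
    NA_real_
  } else {
    integrate_series(series$day, hb) / integrate_series(series$day, total)
  }
  list(daily = daily, season = season)
}

#' Season summary of floral resources and visitation
#'
#' Rolls one season series up into the season-total metrics: flower coverage
#' time (%t, percent-days), pollinator visitation time (pvt, rate-days),
#' visitation intensity (pvt / %t), season flower sum (flowers ha^-1), and
#' the season honey-bee fraction.
#'
#' @param series a `season_series` data.frame (see [simulate_phenology()]);
#'   needs columns `day`, `cover`, and either `total_rate` or the
#'   per-category rate columns; `flower_density_ha` if present feeds the
#'   flower sum.
#' @return A list of class `season_summary` with elements `coverage_time`,
#'   `pvt`, `intensity`, `flower_sum`, `honeybee_fraction`, `treatment`,
#'   `year`.
#' @export
season_summary <- function(series) {
  stopifnot(all(c("day", "cover") %in% names(series)))
  cats <- insect_categories()
  total <- if ("total_rate" %in% names(series)) {
    series$total_rate
  } else {
    rowSums(series[intersect(cats, names(series))])
  }
  ct <- integrate_series(series$day, series$cover)
  pvt <- integrate_series(series$day, total)
  fs <- if ("flower_density_ha" %in% names(series)) {
    season_flower_sum(series$day, series$flower_density_ha)
  } else {
    NA_real_
  }
  hb <- if (all(cats %in% names(series))) honeybee_fraction(series)$season else NA_real_
  structure(
    list(coverage_time = ct, pvt = pvt,
         intensity = if (ct > 0) pvt / ct else NA_real_,
         flower_sum = fs, honeybee_fraction = hb,
         treatment = if ("treatment" %in% names(series)) series$treatment[1] else NA,
         year = if ("year" %in% names(series)) series$year[1] else NA),
    class = "season_summary"
  )
}

#' @export
print.season_summary <- function(x, ...) {
  cat(sprintf("season summary (%s%s)\n",
              ifelse(is.na(x$treatment), "", paste0(x$treatment, " ")),
              ifelse(is.na(x$year), "", x$year)))
  cat(sprintf("  coverage time (%%t) : %.0f percent-days\n", x$coverage_time))
  cat(sprintf("  visitation time pvt: %.0f rate-days\n", x$pvt))
  cat(sprintf("  intensity pvt/%%t  : %.2f\n", x$intensity))
  if (!is.na(x$flower_sum)) {
    cat(sprintf("  season flower sum : %.2f billion ha^-1\n", x$flower_sum / 1e9))
  }
  if (!is.na(x$honeybee_fraction)) {
    cat(sprintf("  honey-bee share   : %.0f%%\n", 100 * x$honeybee_fraction))
  }
  invisible(x)
}
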