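#' Nectar volume from a microcapillary reading
#'
#' Volume is the filled fraction of the capillary times its nominal volume:
#' `(column_length / capillary_length) * capillary_volume`.
#'
#' @param column_length nectar column length, mm.
#' @param capillary_length total capillary length, mm.
#' @param capillary_volume nominal capillary volume, uL (field kits use 1, 5
#'   or 10 uL).
#' @return Nectar volume in uL.
#' @export
nectar_volume <- function(column_length, capillary_length, capillary_volume) {
  if (any(capillary_length <= 0) || any(capillary_volume <= 0)) {
    stop("capillary dimensions must be positive", call. = FALSE)
  }
  if (any(column_length < 0) || any(column_length > capillary_length)) {
    stop("column_length must lie in [0, capillary_length]", call. = FALSE)
  }
  column_length / capillary_length * capillary_volume
}

# Sucrose concentration of nectar, mg per uL, from a refractometer Brix
# reading (percent sucrose w/w). Quadratic Brix-to-mass conversion standard
# in the nectar-chemistry literature.
brix_to_mg_per_ul <- function(brix) {
  0.00226 + 0.00937 * brix + 0.0000585 * brix^2
}

#' Sucrose mass in a nectar sample
#'
#' Converts nectar volume and refractometer concentration into sucrose mass:
#' `mass (ug) = volume (uL) * 1000 * (0.00226 + 0.00937 C + 0.0000585 C^2)`
#' with `C` the Brix reading (percent sucrose). Strictly increasing in both
#' arguments and linear in volume at fixed concentration.
#'
#' @param volume nectar volume, uL (>= 0).
#' @param brix percent sucrose, 0-85 (refractometer range).
#' @return Sucrose mass in ug.
#' @examples
#' sucrose_mass(0.01, 36.2)  # ~4.2 ug, a typical soybean flower
#' @export
sucrose_mass <- function(volume, brix) {
  if (any(volume < 0)) stop("volume must be non-negative", call. = FALSE)
  if (any(brix < 0 | brix > 85)) {
    stop("brix must be in [0, 85]", call. = FALSE)
  }
  volume * 1000 * brix_to_mg_per_ul(brix)
}

#' Daily per-flower sucrose production
#'
#' The protocol measures 2-h sucrose secretion in three intervals spanning
#' the nectar-producing day (0900-1100, 1200-1400, 1500-1700 h); daily
#' production per flower is approximated by the sum of the three interval
#' means.
#'
#' @param interval_means three non-negative mean sucrose masses, ug per 2 h.
#' @return Daily sucrose production, ug d^-1 flower^-1.
#' @export
daily_flower_sucrose <- function(interval_means) {
  if (length(interval_means) != 3) {
    stop("exactly three interval means are required", call. = FALSE)
  }
  if (any(interval_means < 0)) {
    stop("interval means must be non-negative", call. = FALSE)
  }
  sum(interval_means)
}

#' Mean sucrose per sampling interval from nectar records
#'
#' Computes each record's implied sucrose mass (via [nectar_volume()] and
#' [sucrose_mass()]) and averages within interval, pooling flowers across
#' sampling dates with equal weight.
#'
#' @param records nectar record data.frame with columns `interval`,
#'   `capillary_volume_ul`, `capillary_length_mm`, `column_length_mm`,
#'   `brix`.
#' @return Named numeric vector of mean sucrose mass (ug per 2 h) per
#'   interval, in interval order.
#' @export
nectar_interval_means <- function(records) {
  need <- c("interval", "capillary_volume_ul", "capillary_length_mm",
            "column_length_mm", "brix")
  stopifnot(all(need %in% names(records)))
  vol <- nectar_volume(records$column_length_mm, records$capillary_length_mm,
                       records$capillary_volume_ul)
  mass <- sucrose_mass(vol, records$brix)
  means <- tapply(mass, records$interval, mean)
  means[order(names(means))]
}

#' Season sucrose production per hectare
#'
#' Scales per-flower daily sucrose to the hectare-season:
#' `flower_sum * daily / 1e9` kg (ug -> kg), i.e. the season flower sum
#' times what one flower secretes in a day. Assumes every flower produces a
#' full day's nectar, so it is a potential (upper-bound) provision.
#'
#' @param flower_sum season flower sum, flowers ha^-1 season^-1.
#' @param daily daily per-flower sucrose, ug d^-1.
#' @return Sucrose, kg ha^-1 season^-1 (full precision; report to nearest kg).
#' @examples
#' season_sucrose_per_ha(1.01e9, 635)  # ~641 kg
#' @export
season_sucrose_per_ha <- function(flower_sum, daily) {
  if (any(flower_sum < 0) || any(daily < 0)) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  flower_sum * daily / 1e9
}

#' Honey-bee colonies supportable by a season's sucrose
#'
#' A healthy colony consumes roughly 100-200 kg of sugar per year; dividing
#' the season's sucrose by the high and low ends of that requirement brackets
#' the number of hives one hectare could support for a full year.
#'
#' @param season_sucrose kg ha^-1 season^-1.
#' @param annual_need_low,annual_need_high colony sugar requirement bounds,
#'   kg yr^-1 (defaults 100 and 200).
#' @return Named integer vector `c(hives_min, hives_max)`: colonies at the
#'   high and low requirement respectively, rounded to the nearest whole
#'   hive.
#' @examples
#' hives_supported(641)   # 3 to 6 hives
#' @export
hives_supported <- function(season_sucrose, annual_need_low = 100,
                            annual_need_high = 200) {
  if (annual_need_low <= 0 || annual_need_high <= 0 ||
      annual_need_low >= annual_need_high) {
    stop("need 0 < annual_need_low < annual_need_high", call. = FALSE)
  }
  if (any(season_sucrose < 0)) {
    stop("season_sucrose must be non-negative", call. = FALSE)
  }
  c(hives_min = round(season_sucrose / annual_need_high),
    hives_max = round(season_sucrose / annual_need_low))
}

#' Full sucrose budget for one season
#'
#' Chains the nectar arithmetic: interval means from raw records, daily
#' per-flower sucrose, hectare-season sucrose at the given flower sum, and
#' the supportable-hive bracket.
#'
#' @param records nectar records (see [nectar_interval_means()]).
#' @param flower_sum season flower sum, flowers ha^-1 season^-1.
#' @param annual_need_low,annual_need_high passed to [hives_supported()].
#' @return List of class `sucrose_budget`: `interval_means`,
#'   `daily_per_flower` (ug), `season_per_ha` (kg), `hives_min`, `hives_max`.
#' @export
sucrose_budget <- function(records, flower_sum, annual_need_low = 100,
                           annual_need_high = 200) {
  im <- nectar_interval_means(records)
  daily <- daily_flower_sucrose(as.numeric(im))
  season <- season_sucrose_per_ha(flower_sum, daily)
  hives <- hives_supported(season, annual_need_low, annual_need_high)
  structure(list(interval_means = im, daily_per_flower = daily,
                 season_per_ha = season, hives_min = hives[["hives_min"]],
                 hives_max = hives[["hives_max"]]),
            class = "sucrose_budget")
}

#' @export
print.sucrose_budget <- function(x, ...) {
  cat(sprintf("daily per-flower sucrose: %.0f ug d^-1\n", x$daily_per_flower))
  cat(sprintf("season sucrose: %.0f kg ha^-1\n", x$season_per_ha))
  cat(sprintf("supports %d-%d hives for a year\n", x$hives_min, x$hives_max))
  invisible(x)
}
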