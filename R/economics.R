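#' Economic configuration for crop comparison
#'
#' Contract seed price, the net-to-gross return ratio assumed transferable
#' from the reference commodity crops, and the reference net returns to
#' match. Defaults are the 2012 regional figures: $5.30 kg^-1 contract
#' price, net returns at 32% of gross, and median net returns of $894 ha^-1
#' for corn and $526 ha^-1 for soybean.
#'
#' @param seed_price contract seed price, $ kg^-1.
#' @param net_gross_ratio net return as a fraction of gross, in (0, 1].
#' @param reference_net_returns named numeric vector of net returns,
#'   $ ha^-1, by reference crop.
#' @return List of class `econ_config`.
#' @export
econ_config <- function(seed_price = 5.30, net_gross_ratio = 0.32,
                        reference_net_returns = c(corn = 894, soybean = 526)) {
  if (seed_price <= 0) stop("seed_price must be positive", call. = FALSE)
  if (net_gross_ratio <= 0 || net_gross_ratio > 1) {
    stop("net_gross_ratio must be in (0, 1]", call. = FALSE)
  }
  structure(list(seed_price = seed_price, net_gross_ratio = net_gross_ratio,
                 reference_net_returns = reference_net_returns),
            class = "econ_config")
}

#' Gross return from seed yield
#'
#' @param yield seed yield, kg ha^-1.
#' @param price seed price, $ kg^-1.
#' @param rounded round to the nearest dollar (default TRUE, matching
#'   reporting convention).
#' @return Gross return, $ ha^-1.
#' @examples
#' gross_return(327, 5.30)  # $1733
#' @export
gross_return <- function(yield, price, rounded = TRUE) {
  if (any(yield < 0)) stop("yield must be non-negative", call. = FALSE)
  if (any(price <= 0)) stop("price must be positive", call. = FALSE)
  g <- yield * price
  if (rounded) round(g) else g
}

#' Break-even yield to match a reference net return
#'
#' Yield needed so that `yield * price * ratio` equals the target net
#' return: `target_net / ratio / price`.
#'
#' @param target_net net return to match, $ ha^-1.
#' @param ratio net-to-gross return ratio, in (0, 1].
#' @param price seed price, $ kg^-1.
#' @param rounded round to the nearest kg (default TRUE).
#' @return Break-even seed yield, kg ha^-1.
#' @examples
#' breakeven_yield(526, 0.32, 5.30)  # 310 kg to match soybean
#' breakeven_yield(894, 0.32, 5.30)  # 527 kg to match corn
#' @export
breakeven_yield <- function(target_net, ratio, price, rounded = TRUE) {
  if (any(target_net <= 0) || any(ratio <= 0) || any(price <= 0)) {
    stop("all inputs must be positive", call. = FALSE)
  }
  y <- target_net / ratio / price
  if (rounded) round(y) else y
}

#' Mean seed yield by planting class
#'
#' Unweighted arithmetic mean of yields within each planting class
#' (early / mid / late), across years.
#'
#' @param yields data.frame with columns `planting_time` and `yield_kg_ha`
#'   (a `year` column is allowed and ignored).
#' @param rounded round means to the nearest kg (default TRUE).
#' @return Named numeric vector of class means, kg ha^-1, in the order
#'   early, mid, late (classes present only).
#' @export
yield_summary <- function(yields, rounded = TRUE) {
  stopifnot(all(c("planting_time", "yield_kg_ha") %in% names(yields)))
  if (any(is.na(yields$yield_kg_ha))) {
    stop("yields must not contain NA", call. = FALSE)
  }
  cls <- planting_order(yields$planting_time)
  m <- tapply(yields$yield_kg_ha, cls, mean)
  m <- m[!is.na(m)]
  if (length(m) == 0) stop("no yields in any planting class", call. = FALSE)
  out <- as.numeric(m)
  names(out) <- names(m)
  if (rounded) round(out) else out
}

# Factor with the canonical early < mid < late planting order.
planting_order <- function(x) {
  factor(as.character(x), levels = c("early", "mid", "late"))
}
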