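#' Distance-sample container
#'
#' One row per transect sample point: the distance from the point to the
#' nearest open flower, and from that flower to its own nearest neighbouring
#' open flower. Either search can be censored at the field search limit
#' (no flower found within `field_limit`), in which case the distance is `NA`
#' and the corresponding censoring flag is `TRUE`. A censored point search
#' leaves the neighbour fields `NA`.
#'
#' @param point_distance_m,neighbor_distance_m numeric, metres (`NA` when
#'   censored).
#' @param point_censored,neighbor_censored logical flags.
#' @param field_limit maximum search distance in metres (default 0.15, the
#'   field protocol's cap that prevents double-counting flowers).
#' @param date observation date label (day of year or ISO date), recycled.
#' @param point_id sample-point identifiers; defaults to the row sequence.
#'
#' @return A data.frame of class `distance_sample` with columns `date`,
#'   `point_id`, `point_distance_m`, `point_censored`, `neighbor_distance_m`,
#'   `neighbor_censored`, and attribute `field_limit`.
#' @export
distance_sample <- function(point_distance_m, point_censored,
                            neighbor_distance_m, neighbor_censored,
                            field_limit = 0.15, date = NA, point_id = NULL) {
  n <- length(point_distance_m)
  if (is.null(point_id)) point_id <- seq_len(n)
  stopifnot(length(point_censored) == n, length(neighbor_distance_m) == n,
            length(neighbor_censored) == n)
  if (!is.finite(field_limit) || field_limit <= 0) {
    stop("field_limit must be positive", call. = FALSE)
  }
  d <- point_distance_m[!is.na(point_distance_m)]
  r <- neighbor_distance_m[!is.na(neighbor_distance_m)]
  if (any(d < 0) || any(d > field_limit) || any(r < 0) || any(r > field_limit)) {
    stop("distances must lie in [0, field_limit]", call. = FALSE)
  }
  out <- data.frame(date = rep_len(date, n), point_id = point_id,
                    point_distance_m = as.numeric(point_distance_m),
                    point_censored = as.logical(point_censored),
                    neighbor_distance_m = as.numeric(neighbor_distance_m),
                    neighbor_censored = as.logical(neighbor_censored))
  attr(out, "field_limit") <- field_limit
  class(out) <- c("distance_sample", "data.frame")
  out
}

#' Field search limit of a distance sample
#' @param sample a [distance_sample()].
#' @return numeric scalar, metres.
#' @export
field_limit <- function(sample) attr(sample, "field_limit")

#' Sample point-transect distances from a flower pattern
#'
#' Emulates the field protocol: a transect rope with `points_per_transect`
#' pre-marked points `point_spacing` apart is laid `n_transects` times in the
#' plot. At each mark the distance to the nearest open flower is measured; if
#' a flower is found, the distance from that flower to its nearest other open
#' flower is measured too. Both searches stop at `field_limit` (censoring).
#'
#' Transects run parallel to the plot's long axis with a uniformly random
#' origin, constrained to lie fully inside the plot (when the plot is wider
#' than long the rope is laid along the x axis instead). Defaults reproduce
#' the protocol: three 1.8 m transects of six points 30 cm apart per plot and
#' a 15 cm search cap.
#'
#' @param pattern a [flower_pattern()].
#' @param n_transects number of transect placements.
#' @param points_per_transect marks per transect.
#' @param point_spacing mark spacing in metres.
#' @param field_limit maximum search distance in metres.
#' @param date observation date label carried into the sample.
#' @param seed optional integer seed.
#' @return A [distance_sample()] with `n_transects * points_per_transect` rows.
#' @export
sample_transects <- function(pattern, n_transects = 3, points_per_transect = 6,
                             point_spacing = 0.30, field_limit = 0.15,
                             date = NA, seed = NULL) {
  stopifnot(inherits(pattern, "flower_pattern"))
  if (point_spacing <= 0 || field_limit <= 0 || n_transects < 1 ||
      points_per_transect < 1) {
    stop("transect layout parameters must be positive", call. = FALSE)
  }
  tlen <- (points_per_transect - 1) * point_spacing
  w <- pattern$plot_width
  l <- pattern$plot_length
  if (tlen > w && tlen > l) {
    stop("transect is longer than both plot dimensions", call. = FALSE)
  }
  along_y <- l >= w  # lay the rope along the longer axis
  local_seed(seed)
  pts <- do.call(rbind, lapply(seq_len(n_transects), function(i) {
    if (along_y) {
      x0 <- stats::runif(1, 0, w)
      y0 <- stats::runif(1, 0, l - tlen)
      cbind(x0, y0 + (seq_len(points_per_transect) - 1) * point_spacing)
    } else {
      x0 <- stats::runif(1, 0, w - tlen)
      y0 <- stats::runif(1, 0, l)
      cbind(x0 + (seq_len(points_per_transect) - 1) * point_spacing, y0)
    }
  }))

  n <- nrow(pts)
  pd <- rep(NA_real_, n)
  nd <- rep(NA_real_, n)
  pc <- rep(TRUE, n)
  nc <- rep(NA, n)
  xy <- pattern$coords
  if (nrow(xy) > 0) {
    # nearest flower to every sample point in one distance matrix
    d2 <- outer(pts[, 1], xy[, 1], "-")^2 + outer(pts[, 2], xy[, 2], "-")^2
    j <- max.col(-d2, ties.method = "first")
    d <- sqrt(d2[cbind(seq_len(n), j)])
    found <- d <= field_limit
    pd[found] <- d[found]
    pc[found] <- FALSE
    nc[found] <- TRUE
    if (nrow(xy) > 1 && any(found)) {
      # nearest other flower for each distinct found flower
      uj <- unique(j[found])
      d2n <- outer(xy[uj, 1], xy[, 1], "-")^2 + outer(xy[uj, 2], xy[, 2], "-")^2
      d2n[cbind(seq_along(uj), uj)] <- Inf
      dn_u <- sqrt(apply(d2n, 1, min))
      dn <- dn_u[match(j, uj)]
      ok <- found & !is.na(dn) & dn <= field_limit
      nd[ok] <- dn[ok]
      nc[ok] <- FALSE
    }
  }
  distance_sample(pd, pc, nd, nc, field_limit = field_limit, date = date)
}
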