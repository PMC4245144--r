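#' Flower point pattern within a rectangular plot
#'
#' Container for open-flower coordinates inside a `plot_width` x `plot_length`
#' rectangle (metres). Simulated patterns carry the intensity they were
#' generated with as `true_density`, which downstream estimator-validation
#' code treats as ground truth.
#'
#' @param coords two-column numeric matrix of (x, y) positions in metres.
#' @param plot_width,plot_length plot dimensions in metres. Defaults are the
#'   3.1 x 12.2 m field plots the sampling design was built around.
#' @param true_density generating intensity in flowers per square metre, or
#'   `NA` for observed patterns.
#'
#' @return An object of class `flower_pattern`: a list with elements
#'   `coords`, `plot_width`, `plot_length`, `true_density`.
#' @export
flower_pattern <- function(coords, plot_width = 3.1, plot_length = 12.2,
                           true_density = NA_real_) {
  coords <- matrix(as.numeric(coords), ncol = 2,
                   dimnames = list(NULL, c("x", "y")))
  if (!is.finite(plot_width) || !is.finite(plot_length) ||
      plot_width <= 0 || plot_length <= 0) {
    stop("plot dimensions must be positive", call. = FALSE)
  }
  if (nrow(coords) > 0) {
    if (any(coords[, 1] < 0 | coords[, 1] > plot_width |
            coords[, 2] < 0 | coords[, 2] > plot_length)) {
      stop("all coordinates must lie inside the plot", call. = FALSE)
    }
  }
  if (!is.na(true_density) && true_density < 0) {
    stop("true_density must be non-negative", call. = FALSE)
  }
  structure(
    list(coords = coords, plot_width = plot_width, plot_length = plot_length,
         true_density = true_density),
    class = "flower_pattern"
  )
}

#' @export
print.flower_pattern <- function(x, ...) {
  area <- x$plot_width * x$plot_length
  cat(sprintf("flower_pattern: %d flowers in %.1f x %.1f m plot (%.1f m^2)\n",
              nrow(x$coords), x$plot_width, x$plot_length, area))
  cat(sprintf("  realized density %.1f m^-2", nrow(x$coords) / area))
  if (!is.na(x$true_density)) cat(sprintf(", generating density %.1f m^-2", x$true_density))
  cat("\n")
  invisible(x)
}

#' Plot area in square metres
#' @param pattern a [flower_pattern()].
#' @return numeric scalar, m^2.
#' @export
pattern_area <- function(pattern) pattern$plot_width * pattern$plot_length

#' Simulate a completely spatially random (CSR) flower pattern
#'
#' Homogeneous Poisson process: the flower count is Poisson(density x area)
#' and positions are i.i.d. uniform over the plot. CSR is the null model
#' under which simple distance-based density estimators are unbiased, so
#' these patterns are the calibration standard for the estimators in
#' [estimate_point_density()] and friends.
#'
#' @param density intensity in flowers per square metre (>= 0).
#' @param plot_width,plot_length plot dimensions in metres.
#' @param seed optional integer seed; the draw is reproducible given a seed.
#' @return A [flower_pattern()] with `true_density = density`.
#' @examples
#' pat <- simulate_poisson_pattern(50, seed = 1)
#' nrow(pat$coords) / pattern_area(pat)  # close to 50
#' @export
simulate_poisson_pattern <- function(density, plot_width = 3.1,
                                     plot_length = 12.2, seed = NULL) {
  if (!is.finite(density) || density < 0) {
    stop("density must be a non-negative number", call. = FALSE)
  }
  if (plot_width <= 0 || plot_length <= 0) {
    stop("plot dimensions must be positive", call. = FALSE)
  }
  local_seed(seed)
  n <- stats::rpois(1, density * plot_width * plot_length)
  coords <- cbind(stats::runif(n, 0, plot_width), stats::runif(n, 0, plot_length))
  flower_pattern(coords, plot_width, plot_length, true_density = density)
}

#' Simulate a Thomas-cluster flower pattern
#'
#' Clustered alternative to CSR: Poisson(parent_density x area) parent stems,
#' each with a Poisson(mean_offspring) number of flowers displaced by an
#' isotropic Gaussian of standard deviation `cluster_sd`. Offspring falling
#' outside the plot are discarded. The recorded `true_density` is the
#' process intensity `parent_density * mean_offspring` (before edge loss),
#' which is the quantity a density estimator targets.
#'
#' Flowers on a branched cyme cluster tightly around stems, so small
#' `cluster_sd` (a few cm) mimics the within-plot clumping that biases naive
#' distance estimators and that the corrected estimator is designed to absorb.
#' As `cluster_sd` grows beyond the plot size the pattern converges to CSR.
#'
#' @param parent_density parent stems per square metre.
#' @param mean_offspring mean flowers per parent.
#' @param cluster_sd Gaussian displacement SD in metres.
#' @inheritParams simulate_poisson_pattern
#' @return A [flower_pattern()].
#' @export
simulate_thomas_pattern <- function(parent_density, mean_offspring, cluster_sd,
                                    plot_width = 3.1, plot_length = 12.2,
                                    seed = NULL) {
  if (any(!is.finite(c(parent_density, mean_offspring, cluster_sd))) ||
      parent_density < 0 || mean_offspring < 0 || cluster_sd < 0) {
    stop("Thomas process parameters must be non-negative", call. = FALSE)
  }
  if (plot_width <= 0 || plot_length <= 0) {
    stop("plot dimensions must be positive", call. = FALSE)
  }
  local_seed(seed)
  n_parents <- stats::rpois(1, parent_density * plot_width * plot_length)
  px <- stats::runif(n_parents, 0, plot_width)
  py <- stats::runif(n_parents, 0, plot_length)
  n_off <- stats::rpois(n_parents, mean_offspring)
  total <- sum(n_off)
  x <- rep(px, n_off) + stats::rnorm(total, 0, cluster_sd)
  y <- rep(py, n_off) + stats::rnorm(total, 0, cluster_sd)
  keep <- x >= 0 & x <= plot_width & y >= 0 & y <= plot_length
  flower_pattern(cbind(x[keep], y[keep]), plot_width, plot_length,
                 true_density = parent_density * mean_offspring)
}

#' Quadrat counts for a flower pattern
#'
#' Counts flowers in an `nx` x `ny` grid of equal rectangular quadrats.
#' The variance/mean ratio of these counts is the standard dispersion
#' diagnostic: 1 under CSR, > 1 for clustered patterns.
#'
#' @param pattern a [flower_pattern()].
#' @param nx,ny number of grid cells along each axis.
#' @return Integer vector of `nx * ny` counts.
#' @export
quadrat_counts <- function(pattern, nx = 4, ny = 12) {
  ix <- pmin(floor(pattern$coords[, 1] / pattern$plot_width * nx), nx - 1)
  iy <- pmin(floor(pattern$coords[, 2] / pattern$plot_length * ny), ny - 1)
  as.integer(tabulate(ix * ny + iy + 1, nbins = nx * ny))
}

# Reseed the session RNG when a seed is supplied; seed = NULL leaves the
# RNG stream untouched (the usual convention for simulation functions).
local_seed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  set.seed(as.integer(seed))
  invisible(NULL)
}
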