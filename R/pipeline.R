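#' Configuration for a full synthetic-season pipeline run
#'
#' Collects every knob of the simulate -> density -> phenology -> nectar ->
#' economics -> report chain, with one master seed from which each stage
#' derives its own reproducible seed.
#'
#' @param seed master integer seed; stage seeds are `seed * 1000 + k` for
#'   small stage offsets `k`, so keep `seed` below about 2 million.
#' @param year season label.
#' @param treatments named list of [phenology_params()], one per sowing
#'   treatment (names become planting-time labels; use early/mid/late).
#' @param noise_cv observation-noise CV for the phenology simulator.
#' @param n_density_dates number of transect observation dates spread over
#'   each treatment's anthesis window.
#' @param n_transects transect placements per date (6-point transects; 12
#'   placements give the standard 72 sample points).
#' @param cluster_sd,mean_offspring Thomas-process clustering of the
#'   simulated flower patterns (set `cluster_sd = Inf` for Poisson/CSR).
#' @param exclude_fraction,level,n_boot corrected-density estimator options.
#' @param nectar_interval_means,nectar_brix,nectar_cv,nectar_flowers nectar
#'   generator settings (see [simulate_nectar_records()]).
#' @param econ an [econ_config()].
#' @param yields optional data.frame in the `yields` schema giving a seed
#'   yield per treatment.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, year = 1L,
                       treatments = list(
                         early = phenology_params(),
                         late = phenology_params(days_to_first_flower = 46,
                                                 anthesis_duration = 48,
                                                 peak_density = 2.4e7,
                                                 sowing_doy = 189)),
                       noise_cv = 0.15, n_density_dates = 5, n_transects = 12,
                       cluster_sd = 0.08, mean_offspring = 20,
                       exclude_fraction = 0.30, level = 0.95, n_boot = 500,
                       nectar_interval_means = c(170, 295, 170),
                       nectar_brix = 34, nectar_cv = 0.2, nectar_flowers = 10,
                       econ = econ_config(), yields = NULL) {
  stopifnot(length(treatments) >= 1, !is.null(names(treatments)))
  structure(as.list(environment()), class = "run_config")
}

#' Run the full synthetic-field pipeline
#'
#' Simulates one season per treatment, estimates flower density from
#' simulated transect distance records on several dates, integrates the
#' season metrics, builds the nectar sucrose budget, applies the economics,
#' and writes the output tables to `out_dir`:
#' `phenology.csv`, `visitation.csv`, `distance_records.csv`, `nectar.csv`,
#' `density_estimates.csv`, `season_report.csv`, and a `manifest.txt` with
#' one line per stage (inputs, parameters, seeds, row counts; no
#' timestamps). Identical configurations produce byte-identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the report data.frame and the per-date
#'   density estimates.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- file.path(out_dir, "manifest.txt")
  if (file.exists(manifest)) unlink(manifest)
  sseed <- function(k) config$seed * 1000 + k

  phen_rows <- list()
  vis_rows <- list()
  dist_rows <- list()
  dens_rows <- list()
  report_rows <- list()
  k <- 0
  for (tr in names(config$treatments)) {
    k <- k + 1
    params <- config$treatments[[tr]]
    series <- simulate_phenology(params, noise_cv = config$noise_cv,
                                 treatment = tr, year = config$year,
                                 seed = sseed(k))
    phen_rows[[tr]] <- data.frame(date = series$day, plot = tr,
                                  cover_pct = series$cover,
                                  flower_density_ha = series$flower_density_ha)
    vis <- series[c("day", insect_categories(), "observers", "minutes")]
    names(vis)[1] <- "date"
    vis$plot <- tr
    vis_rows[[tr]] <- vis[c("date", "plot", "observers", "minutes",
                            insect_categories())]

    # transect sampling on dates spread through anthesis
    obs_days <- round(seq(2, params$anthesis_duration - 2,
                          length.out = config$n_density_dates))
    for (j in seq_along(obs_days)) {
      day_idx <- which.min(abs(series$days_since_first_flower - obs_days[j]))
      dens_m2 <- series$flower_density_ha[day_idx] / 1e4
      pat_seed <- sseed(100 + 10 * k + j)
      pat <- if (is.finite(config$cluster_sd)) {
        simulate_thomas_pattern(dens_m2 / config$mean_offspring,
                                config$mean_offspring, config$cluster_sd,
                                seed = pat_seed)
      } else {
        simulate_poisson_pattern(dens_m2, seed = pat_seed)
      }
      smp <- sample_transects(pat, n_transects = config$n_transects,
                              date = series$day[day_idx],
                              seed = pat_seed + 1)
      rec <- as.data.frame(smp)
      rec$plot <- tr
      dist_rows[[paste(tr, j)]] <- rec
      est <- tryCatch(
        estimate_density(smp, exclude_fraction = config$exclude_fraction,
                         level = config$level, n_boot = config$n_boot,
                         seed = pat_seed + 2),
        warning = function(w) NULL, error = function(e) NULL)
      if (!is.null(est)) {
        dens_rows[[paste(tr, j)]] <- data.frame(
          plot = tr, date = est$date, d_corrected_m2 = est$d_corrected,
          per_ha = est$per_ha, ci_low_ha = est$ci_low, ci_high_ha = est$ci_high,
          se_ha = est$se, trunc_radius_m = est$trunc_radius,
          n_points = est$n_points, n_used = est$n_used)
      }
    }

    summ <- season_summary(series)
    nect <- simulate_nectar_records(config$nectar_flowers,
                                    config$nectar_interval_means,
                                    config$nectar_brix, config$nectar_cv,
                                    seed = sseed(500 + k))
    nect$plot <- tr
    budget <- sucrose_budget(nect, summ$flower_sum)
    yield <- NA_real_
    if (!is.null(config$yields)) {
      hit <- config$yields$planting_time == tr
      if (any(hit)) yield <- config$yields$yield_kg_ha[which(hit)[1]]
    }
    report_rows[[tr]] <- list(summary = summ, budget = budget,
                              yield_kg_ha = yield, nectar = nect)
    write_manifest_line(manifest, paste0("simulate:", tr),
                        seed = sseed(k), noise_cv = config$noise_cv,
                        days = nrow(series))
  }

  phen <- do.call(rbind, phen_rows)
  vis <- do.call(rbind, vis_rows)
  dist <- do.call(rbind, dist_rows)
  dens <- do.call(rbind, dens_rows)
  nect_all <- do.call(rbind, lapply(report_rows, `[[`, "nectar"))
  utils::write.csv(phen, file.path(out_dir, "phenology.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(vis, file.path(out_dir, "visitation.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(dist, file.path(out_dir, "distance_records.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(dens, file.path(out_dir, "density_estimates.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(nect_all, file.path(out_dir, "nectar.csv"),
                   row.names = FALSE, quote = FALSE)
  write_manifest_line(manifest, "density", dates = nrow(dens),
                      n_boot = config$n_boot,
                      exclude_fraction = config$exclude_fraction)
  write_manifest_line(manifest, "nectar", rows = nrow(nect_all),
                      brix = config$nectar_brix)

  report <- report_summary(report_rows, config = config$econ,
                           path = file.path(out_dir, "season_report.csv"))
  write_manifest_line(manifest, "report", rows = nrow(report),
                      seed = config$seed)
  invisible(list(report = report, density = dens))
}
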