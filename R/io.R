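#' Record schemas for the field CSV files
#'
#' Column sets and row-level validity rules for the five tidy CSV record
#' types the pipeline consumes:
#' \describe{
#'   \item{distance}{`date, point_id, point_distance_m, point_censored,
#'     neighbor_distance_m, neighbor_censored` — transect distance records.}
#'   \item{phenology}{`date, plot, cover_pct, flower_density_ha` — percent
#'     flower cover (0-100) and open-flower density.}
#'   \item{visitation}{`date, plot, observers, minutes` plus one count
#'     column per [insect_categories()].}
#'   \item{nectar}{`flower_id, date, interval, capillary_volume_ul,
#'     capillary_length_mm, column_length_mm, brix` — microcapillary
#'     measurements, Brix 0-85.}
#'   \item{yields}{`year, planting_time, yield_kg_ha` — harvest yields by
#'     sowing treatment.}
#' }
#'
#' @return Named list; each element has `columns` (required names) and
#'   `rules` (named list of per-row predicate functions, TRUE = valid).
#' @export
record_schemas <- function() {
  list(
    distance = list(
      columns = c("date", "point_id", "point_distance_m", "point_censored",
                  "neighbor_distance_m", "neighbor_censored"),
      rules = list(
        point_distance_m = function(df)
          is.na(df$point_distance_m) | df$point_distance_m >= 0,
        neighbor_distance_m = function(df)
          is.na(df$neighbor_distance_m) | df$neighbor_distance_m >= 0
      )
    ),
    phenology = list(
      columns = c("date", "plot", "cover_pct", "flower_density_ha"),
      rules = list(
        cover_pct = function(df)
          !is.na(df$cover_pct) & df$cover_pct >= 0 & df$cover_pct <= 100,
        flower_density_ha = function(df)
          is.na(df$flower_density_ha) | df$flower_density_ha >= 0
      )
    ),
    visitation = list(
      columns = c("date", "plot", "observers", "minutes", insect_categories()),
      rules = c(
        list(
          observers = function(df) !is.na(df$observers) & df$observers >= 1,
          minutes = function(df) !is.na(df$minutes) & df$minutes > 0
        ),
        stats::setNames(lapply(insect_categories(), function(cc) {
          force(cc)
          function(df) !is.na(df[[cc]]) & df[[cc]] >= 0
        }), insect_categories())
      )
    ),
    nectar = list(
      columns = c("flower_id", "date", "interval", "capillary_volume_ul",
                  "capillary_length_mm", "column_length_mm", "brix"),
      rules = list(
        brix = function(df) !is.na(df$brix) & df$brix >= 0 & df$brix <= 85,
        column_length_mm = function(df)
          !is.na(df$column_length_mm) & df$column_length_mm >= 0 &
            df$column_length_mm <= df$capillary_length_mm,
        capillary_volume_ul = function(df)
          !is.na(df$capillary_volume_ul) & df$capillary_volume_ul > 0
      )
    ),
    yields = list(
      columns = c("year", "planting_time", "yield_kg_ha"),
      rules = list(
        yield_kg_ha = function(df)
          !is.na(df$yield_kg_ha) & df$yield_kg_ha >= 0,
        planting_time = function(df)
          df$planting_time %in% c("early", "mid", "late")
      )
    )
  )
}

#' Read and validate a field-record CSV
#'
#' Reads one of the five record schemas, errors if required columns are
#' missing, drops rows that violate a validity rule (reporting each dropped
#' row and the offending column), and logs read/rejected counts.
#'
#' @param path CSV file path.
#' @param schema_name one of `names(record_schemas())`.
#' @param quiet suppress the row-count message (default FALSE).
#' @return Validated data.frame with attributes `n_read` and `n_rejected`.
#' @export
read_records <- function(path, schema_name, quiet = FALSE) {
  schemas <- record_schemas()
  if (!schema_name %in% names(schemas)) {
    stop("unknown schema '", schema_name, "'; expected one of: ",
         paste(names(schemas), collapse = ", "), call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  schema <- schemas[[schema_name]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(schema$columns, names(df))
  if (length(missing) > 0) {
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n_read <- nrow(df)
  bad <- rep(FALSE, n_read)
  if (n_read > 0) {
    for (col in names(schema$rules)) {
      ok <- schema$rules[[col]](df)
      viol <- which(!ok & !bad)
      if (length(viol) > 0 && !quiet) {
        for (i in viol) {
          message("rejecting row ", i, ": invalid value in column '", col, "'")
        }
      }
      bad <- bad | !ok
    }
  }
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  if (n_read == 0) warning("empty file (header only): ", basename(path),
                           call. = FALSE)
  if (!quiet) {
    message(schema_name, " records: ", n_read, " read, ", sum(bad), " rejected")
  }
  attr(out, "n_read") <- n_read
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Distance sample from a validated distance-record table
#'
#' @param records data.frame in the `distance` schema (see
#'   [record_schemas()]), typically from [read_records()].
#' @param field_limit field search limit in metres.
#' @return A [distance_sample()].
#' @export
distance_sample_from_records <- function(records, field_limit = 0.15) {
  distance_sample(records$point_distance_m, records$point_censored,
                  records$neighbor_distance_m, records$neighbor_censored,
                  field_limit = field_limit, date = records$date,
                  point_id = records$point_id)
}

#' Filter visitation records by observation-weather eligibility
#'
#' Insect counts are comparable only in flight-friendly conditions: wind
#' below 7 m s^-1 and either temperature above 5 C with at least half-clear
#' sky, or temperature above 10 C under any sky. Requires `wind_ms`,
#' `temp_c`, `sky_clear_pct` columns; the number of excluded rows is logged.
#'
#' @param records visitation data.frame with the three weather columns.
#' @param quiet suppress the log message.
#' @return The eligible subset.
#' @export
filter_weather_eligible <- function(records, quiet = FALSE) {
  need <- c("wind_ms", "temp_c", "sky_clear_pct")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0) {
    stop("weather filter needs column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ok <- records$wind_ms < 7 &
    ((records$temp_c > 5 & records$sky_clear_pct >= 50) | records$temp_c > 10)
  ok[is.na(ok)] <- FALSE
  if (!quiet) {
    message("weather filter: ", sum(!ok), " of ", nrow(records),
            " observation(s) excluded")
  }
  records[ok, , drop = FALSE]
}

#' Assemble and write the season report table
#'
#' One row per year x planting time with the season metrics at reporting
#' precision: coverage time and pvt to whole units, intensity to 2 decimals,
#' flower sum to 2 decimals in billions, sucrose to the nearest kg, and the
#' economics columns to whole dollars/kg. Rows are sorted by year then by
#' planting order early < mid < late.
#'
#' @param rows list of per-season entries; each entry is a list with
#'   `summary` (a [season_summary()]), and optionally `budget` (a
#'   [sucrose_budget()]), `yield_kg_ha`.
#' @param config an [econ_config()] used for gross returns when yields are
#'   present.
#' @param path optional CSV output path.
#' @return The report data.frame (invisibly written to `path` if given).
#' @export
report_summary <- function(rows, config = econ_config(), path = NULL) {
  if (length(rows) == 0) stop("at least one summary is required", call. = FALSE)
  tab <- do.call(rbind, lapply(rows, function(e) {
    s <- e$summary
    stopifnot(inherits(s, "season_summary"))
    yield <- e$yield_kg_ha %||% NA_real_
    data.frame(
      year = s$year,
      planting_time = s$treatment,
      coverage_time = round(s$coverage_time),
      pvt = round(s$pvt),
      intensity = round(s$intensity, 2),
      flower_sum_billion = if (is.na(s$flower_sum)) NA_real_
                           else round(s$flower_sum / 1e9, 2),
      sucrose_kg_ha = if (is.null(e$budget)) NA_real_
                      else round(e$budget$season_per_ha),
      hives_min = if (is.null(e$budget)) NA_real_ else e$budget$hives_min,
      hives_max = if (is.null(e$budget)) NA_real_ else e$budget$hives_max,
      yield_kg_ha = if (is.na(yield)) NA_real_ else round(yield),
      gross_return_usd = if (is.na(yield)) NA_real_
                         else gross_return(yield, config$seed_price)
    )
  }))
  ord <- order(tab$year, planting_order(tab$planting_time))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  }
  invisible(tab)
}

# Append one deterministic manifest line per pipeline stage (no timestamps,
# so that identical runs give byte-identical outputs).
write_manifest_line <- function(manifest_path, stage, ...) {
  kv <- list(...)
  line <- paste0("stage=", stage,
                 if (length(kv) > 0) paste0(" ", paste(names(kv), unlist(kv),
                                                       sep = "=", collapse = " "))
                 else "")
  cat(line, "\n", file = manifest_path, append = TRUE, sep = "")
}
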