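#' Build a pipeline run configuration
#'
#' Exactly one input source must be supplied: a [synthetic_scenario()], or
#' paths to a profile CSV (fixture dialect, see [read_profiles_csv()]) plus
#' optionally a satellite series CSV. All correction toggles are recorded
#' verbatim in the report so a run can be reproduced bit-identically.
#'
#' @param scenario a [synthetic_scenario()], or `NULL` for real inputs.
#' @param profiles_csv,satellite_csv input paths for real-format runs.
#' @param corrections list of toggles passed to [derive_all()]. For scenario
#'   runs the default calibration factor is 1, because the generator emits
#'   chlorophyll already in calibrated units; for real fluorometric input the
#'   default factor is 2.
#' @param period_days compositing period (default 5).
#' @param threshold_rule threshold convention, see [compute_threshold()].
#' @param output_dir directory for report and series files, or `NULL` to
#'   skip writing.
#' @param seed overrides the scenario seed when not `NULL`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(scenario = NULL, profiles_csv = NULL,
                       satellite_csv = NULL, corrections = list(),
                       period_days = 5L,
                       threshold_rule = c("relative", "absolute"),
                       output_dir = NULL, seed = NULL) {
  if (is.null(scenario) == is.null(profiles_csv)) {
    bp_stop("invalid_config",
            "supply exactly one of `scenario` or `profiles_csv`")
  }
  default_factor <- if (is.null(scenario)) 2 else 1
  corrections <- utils::modifyList(list(calibration_factor = default_factor),
                                   corrections)
  structure(list(scenario = scenario, profiles_csv = profiles_csv,
                 satellite_csv = satellite_csv, corrections = corrections,
                 period_days = as.integer(period_days),
                 threshold_rule = match.arg(threshold_rule),
                 output_dir = output_dir, seed = seed),
            class = "run_config")
}

#' Run the full phenology pipeline
#'
#' Ingests profiles and satellite matchups (real-format CSV or a synthetic
#' scenario), applies the correction chain, derives per-profile scalars,
#' builds the three analysis series — satellite surface, float surface
#' (averaged over the first optical depth) and float integrated (surface to
#' euphotic depth) — as gap-filled composites on a shared bin grid, detects
#' phenology independently per series (each with its own threshold), and
#' assembles a comparison report with pairwise timing differences and rank
#' correlations. Flags are data, not failures: only unreadable inputs or
#' unfillable series raise errors.
#'
#' @param config a [run_config()].
#' @return an object of class `comparison_report`: `config_echo`, `n_profiles`,
#'   `n_matchups`, `metrics` (list of `phenology_metrics` per source),
#'   `timing_differences` (pairwise, in periods), `correlations`, `series`,
#'   `derived` (per-profile data.frame), and `truth` for scenario runs.
#'   Written to `output_dir` as `report.json`, `metrics.csv` and
#'   `series/*.csv` when configured.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) bp_stop("invalid_config", "not a run_config")
  truth <- NULL
  if (!is.null(config$scenario)) {
    sc <- config$scenario
    if (!is.null(config$seed)) sc$seed <- as.integer(config$seed)
    gen <- generate_profile_series(sc)
    profiles <- gen$profiles
    truth <- gen$truth
    sat <- generate_satellite_series(sc, gen)
    origin <- sc$start_date
    n_periods <- ceiling(sc$n_days / config$period_days)
  } else {
    profiles <- read_profiles_csv(config$profiles_csv)
    sat <- if (!is.null(config$satellite_csv)) read_satellite_csv(config$satellite_csv)
    origin <- as.Date(min(vapply(profiles, function(p) as.character(as.Date(p$timestamp)), "")))
    last <- as.Date(max(vapply(profiles, function(p) as.character(as.Date(p$timestamp)), "")))
    n_periods <- ceiling((as.numeric(last - origin) + 1) / config$period_days)
  }

  derived <- lapply(profiles, derive_all, corrections = config$corrections)
  ddf <- derived_to_df(derived)

  build <- function(dates, values, source) {
    s <- bin_composites(dates, values, origin_date = origin,
                        period_days = config$period_days,
                        n_periods = n_periods, source = source)
    fill_gaps(s)
  }
  series <- list(
    argo_surf = build(ddf$timestamp, ddf$chl_surf, "argo_surf"),
    argo_int = build(ddf$timestamp, ddf$chl_int, "argo_int"))
  n_matchups <- 0L
  if (!is.null(sat)) {
    mv <- matchup_values(sat)
    n_matchups <- sum(!is.na(mv))
    series$sat_surf <- build(sat$date, mv, "sat_surf")
  }
  series <- series[intersect(c("sat_surf", "argo_surf", "argo_int"), names(series))]

  metrics <- lapply(series, detect_metrics, threshold_rule = config$threshold_rule)

  pairs <- utils::combn(names(series), 2, simplify = FALSE)
  timing_differences <- lapply(pairs, function(p) {
    c(list(from = p[1], to = p[2]),
      compare_timings(metrics[[p[1]]], metrics[[p[2]]]))
  })
  correlations <- lapply(pairs, function(p) {
    r <- tryCatch(rank_correlation(series[[p[1]]], series[[p[2]]]),
                  bloomphen_error = function(e) list(rho = NA_real_, n = 0L, p = NA_real_))
    c(list(from = p[1], to = p[2]), r)
  })

  report <- structure(list(
    config_echo = echo_config(config),
    n_profiles = length(profiles), n_matchups = n_matchups,
    metrics = metrics, timing_differences = timing_differences,
    correlations = correlations, series = series, derived = ddf,
    truth = truth,
    version = as.character(utils::packageVersion("bloomphen"))),
    class = "comparison_report")

  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

# plain-list echo of the config for the report (schedules are functions and
# are represented by their custom/default status)
echo_config <- function(config) {
  sc <- config$scenario
  list(
    input = if (is.null(sc)) list(profiles_csv = config$profiles_csv,
                                  satellite_csv = config$satellite_csv)
    else {
      s <- unclass(sc)
      s$scm_depth_schedule <- s$scm_amplitude_schedule <- s$mld_schedule <- NULL
      s$start_date <- format(s$start_date, "%Y-%m-%d")
      s$depth_grid <- sprintf("%g..%g (%d levels)", min(s$depth_grid),
                              max(s$depth_grid), length(s$depth_grid))
      s
    },
    corrections = config$corrections,
    period_days = config$period_days,
    threshold_rule = config$threshold_rule,
    seed = config$seed)
}

#' Signed timing differences between two detections
#'
#' Differences `b - a` of the initiation, peak and termination bin indices,
#' in composite periods. Metrics absent in either detection propagate as
#' `NA`.
#'
#' @param a,b `phenology_metrics` computed on series sharing origin and
#'   period.
#' @return list with `initiation`, `peak`, `termination` (integers, periods).
#' @export
compare_timings <- function(a, b) {
  if (a$origin_date != b$origin_date || a$period_days != b$period_days) {
    bp_stop("invalid_argument", "metrics do not share origin/period")
  }
  list(initiation = b$initiation_index - a$initiation_index,
       peak = b$peak_index - a$peak_index,
       termination = b$termination_index - a$termination_index)
}

#' Write a comparison report to disk
#'
#' Emits `report.json` (config echo, metrics, timing differences,
#' correlations — no wall-clock timestamps, so identical runs produce
#' byte-identical files), `metrics.csv` (one row per source) and
#' `series/<source>.csv` diagnostic series.
#'
#' @param report a `comparison_report` from [run_pipeline()].
#' @param dir output directory, created if needed.
#' @export
write_report <- function(report, dir) {
  dir.create(file.path(dir, "series"), recursive = TRUE, showWarnings = FALSE)
  body <- list(
    config = report$config_echo,
    n_profiles = report$n_profiles, n_matchups = report$n_matchups,
    metrics = lapply(report$metrics, metrics_row),
    timing_differences = report$timing_differences,
    correlations = report$correlations,
    version = report$version)
  jsonlite::write_json(body, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  mdf <- do.call(rbind, lapply(names(report$metrics), function(nm) {
    as.data.frame(metrics_row(report$metrics[[nm]]), stringsAsFactors = FALSE)
  }))
  utils::write.csv(mdf, file.path(dir, "metrics.csv"), row.names = FALSE, na = "")
  for (nm in names(report$series)) {
    write_series_csv(report$series[[nm]], file.path(dir, "series", paste0(nm, ".csv")))
    utils::write.csv(
      data.frame(bin_index = seq_along(report$metrics[[nm]]$anomalies) - 1L,
                 anomalies = report$metrics[[nm]]$anomalies,
                 cumsum = report$metrics[[nm]]$cumsum,
                 gradient = report$metrics[[nm]]$gradient),
      file.path(dir, "series", paste0(nm, "_diagnostics.csv")),
      row.names = FALSE, na = "")
  }
  invisible(dir)
}

metrics_row <- function(m) {
  list(source = m$source, threshold = m$threshold,
       initiation_index = m$initiation_index, peak_index = m$peak_index,
       termination_index = m$termination_index,
       initiation_date = format(m$initiation_date, "%Y-%m-%d"),
       peak_date = format(m$peak_date, "%Y-%m-%d"),
       termination_date = format(m$termination_date, "%Y-%m-%d"),
       duration_periods = m$duration_periods,
       flags = paste(m$flags, collapse = ";"))
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d profiles, %d matchups, sources: %s\n",
              x$n_profiles, x$n_matchups, paste(names(x$metrics), collapse = ", ")))
  for (nm in names(x$metrics)) print(x$metrics[[nm]])
  for (td in x$timing_differences) {
    cat(sprintf("  %s -> %s: initiation %+d, peak %+d, termination %+d periods\n",
                td$from, td$to,
                td$initiation %||% NA, td$peak %||% NA, td$termination %||% NA))
  }
  for (r in x$correlations) {
    cat(sprintf("  rho(%s, %s) = %.3f (n = %d, p = %.3g)\n",
                r$from, r$to, r$rho, r$n, r$p))
  }
  invisible(x)
}
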