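#' Write profiles to the fixture CSV dialect
#'
#' One row per (profile, depth): columns `profile_id`, `timestamp`
#' (ISO-8601), `lon`, `lat`, `depth_m`, `pres_dbar`, `temp_C`, `psal`,
#' `sigma_kg_m3`, `chl_mg_m3`, `do_umol_kg`, `par`, `bbp700_m1`. Empty cells
#' are missing values; wholly absent variables become empty columns.
#'
#' @param profiles list of [vertical_profile()] objects.
#' @param path output CSV path.
#' @export
write_profiles_csv <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    n <- length(p$depth)
    get <- function(v) if (is.null(v)) rep(NA_real_, n) else v
    data.frame(profile_id = p$profile_id,
               timestamp = format(p$timestamp, "%Y-%m-%d"),
               lon = p$lon, lat = p$lat, depth_m = p$depth,
               pres_dbar = get(p$pressure), temp_C = get(p$temperature),
               psal = get(p$salinity), sigma_kg_m3 = get(p$density),
               chl_mg_m3 = get(p$chl), do_umol_kg = get(p$do),
               par = get(p$par), bbp700_m1 = get(p$bbp700))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read profiles from the fixture CSV dialect
#'
#' Inverse of [write_profiles_csv()]. Variables whose column is entirely
#' empty are treated as absent.
#'
#' @param path CSV path.
#' @return list of [vertical_profile()] objects, ordered by timestamp.
#' @export
read_profiles_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("profile_id", "timestamp", "depth_m")
  if (!all(need %in% names(df))) {
    bp_stop("invalid_input", paste("profile CSV lacks columns:",
                                   paste(setdiff(need, names(df)), collapse = ", ")))
  }
  ids <- unique(df$profile_id)
  profiles <- lapply(ids, function(id) {
    d <- df[df$profile_id == id, ]
    d <- d[order(d$depth_m), ]
    pick <- function(col) {
      v <- d[[col]]
      if (is.null(v) || all(is.na(v))) NULL else as.numeric(v)
    }
    vertical_profile(profile_id = id, timestamp = as.Date(d$timestamp[1]),
                     lon = d$lon[1], lat = d$lat[1], depth = d$depth_m,
                     pressure = pick("pres_dbar"), temperature = pick("temp_C"),
                     salinity = pick("psal"), density = pick("sigma_kg_m3"),
                     chl = pick("chl_mg_m3"), do = pick("do_umol_kg"),
                     par = pick("par"), bbp700 = pick("bbp700_m1"))
  })
  profiles[order(vapply(profiles, function(p) as.numeric(p$timestamp), 0))]
}

#' Write per-profile derived scalars to CSV
#'
#' One row per profile: identifiers, all derived scalars and the
#' semicolon-joined flags.
#'
#' @param derived list of `profile_derived` objects from [derive_all()].
#' @param path output CSV path.
#' @export
write_derived_csv <- function(derived, path) {
  df <- derived_to_df(derived)
  df$timestamp <- format(df$timestamp, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

derived_to_df <- function(derived) {
  do.call(rbind, lapply(derived, function(d) {
    data.frame(profile_id = d$profile_id, timestamp = as.Date(d$timestamp),
               zeu = d$zeu, fod = d$fod, chl_surf = d$chl_surf,
               chl_int = d$chl_int, mld = d$mld, chl_deep = d$chl_deep,
               flags = paste(d$flags, collapse = ";"))
  }))
}

#' Write a composite series to CSV
#'
#' Columns `bin_index` (0-based), `bin_start_date`, `value`, `was_gap`, plus
#' constant `source` and `period_days` columns so the file round-trips.
#'
#' @param series a [chl_timeseries()].
#' @param path output CSV path.
#' @export
write_series_csv <- function(series, path) {
  df <- data.frame(bin_index = seq_along(series$values) - 1L,
                   bin_start_date = format(bin_dates(series), "%Y-%m-%d"),
                   value = series$values, was_gap = series$gap_mask,
                   source = series$source, period_days = series$period_days)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a composite series written by [write_series_csv()]
#' @param path CSV path.
#' @return a [chl_timeseries()].
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  chl_timeseries(df$value, origin_date = as.Date(df$bin_start_date[1]),
                 period_days = df$period_days[1], gap_mask = df$was_gap,
                 source = df$source[1])
}

#' Write a synthetic satellite series to CSV
#' @param sat a `satellite_series` data.frame.
#' @param path output CSV path.
#' @export
write_satellite_csv <- function(sat, path) {
  out <- sat
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a satellite series CSV written by [write_satellite_csv()]
#' @param path CSV path.
#' @return a `satellite_series` data.frame.
#' @export
read_satellite_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  class(df) <- c("satellite_series", "data.frame")
  df
}

#' Serialise a scenario to JSON
#'
#' Schedules are functions and cannot be serialised; scenarios using custom
#' schedules are written with a `custom_schedules` marker and re-read with
#' the defaults, which is flagged with a warning.
#'
#' @param scenario a [synthetic_scenario()].
#' @param path output JSON path.
#' @export
write_scenario_json <- function(scenario, path) {
  sc <- unclass(scenario)
  sc$scm_depth_schedule <- sc$scm_amplitude_schedule <- sc$mld_schedule <- NULL
  sc$custom_schedules <- isTRUE(sc$schedules_custom)
  sc$schedules_custom <- NULL
  sc$start_date <- format(sc$start_date, "%Y-%m-%d")
  jsonlite::write_json(sc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scenario from JSON written by [write_scenario_json()]
#' @param path JSON path.
#' @return a [synthetic_scenario()].
#' @export
read_scenario_json <- function(path) {
  sc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (isTRUE(sc$custom_schedules)) {
    bp_warn("custom_schedules_lost",
            "scenario was saved with custom schedules; defaults restored")
  }
  sc$custom_schedules <- NULL
  sc$start_date <- as.Date(sc$start_date)
  do.call(synthetic_scenario, sc)
}
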