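#' Construct a composite chlorophyll time series
#'
#' A `chl_timeseries` is a regular sequence of composite chlorophyll values
#' anchored at `origin_date`: bin `k` (0-based) covers the half-open day
#' interval `[origin + k*period, origin + (k+1)*period)`. `gap_mask` records
#' which bins were empty before gap filling; after [fill_gaps()] no missing
#' values remain but the mask still marks the interpolated bins.
#'
#' @param values numeric vector, mg m^-3 (surface series) or mg m^-2
#'   (integrated series); `NA` marks missing bins; non-missing values must be
#'   `>= 0`.
#' @param origin_date `Date` of the start of bin 0.
#' @param period_days compositing period in days (default 5).
#' @param gap_mask logical vector, same length as `values`; defaults to
#'   `is.na(values)`.
#' @param source provenance tag: `"sat_surf"`, `"argo_surf"`, `"argo_int"` or
#'   `"custom"`.
#' @return an object of class `chl_timeseries`.
#' @export
chl_timeseries <- function(values, origin_date, period_days = 5L,
                           gap_mask = is.na(values), source = "custom") {
  values <- as.numeric(values)
  if (length(values) < 1) bp_stop("invalid_series", "empty series")
  if (length(gap_mask) != length(values)) {
    bp_stop("invalid_series", "`gap_mask` and `values` lengths differ")
  }
  if (period_days < 1) bp_stop("invalid_series", "`period_days` must be >= 1")
  if (any(values < 0, na.rm = TRUE)) {
    bp_stop("invalid_series", "chlorophyll values must be >= 0")
  }
  source <- match.arg(source, c("sat_surf", "argo_surf", "argo_int", "custom"))
  structure(list(values = values, origin_date = as.Date(origin_date),
                 period_days = as.integer(period_days),
                 gap_mask = as.logical(gap_mask), source = source),
            class = "chl_timeseries")
}

#' @export
print.chl_timeseries <- function(x, ...) {
  cat(sprintf("<chl_timeseries %s> %d bins of %d days from %s (%d gaps)\n",
              x$source, length(x$values), x$period_days,
              format(x$origin_date), sum(x$gap_mask)))
  invisible(x)
}

#' @export
length.chl_timeseries <- function(x) length(x$values)

# start date of each bin
bin_dates <- function(ts) {
  ts$origin_date + (seq_along(ts$values) - 1L) * ts$period_days
}

#' Bin irregular samples into fixed-period composites
#'
#' Averages irregularly sampled observations into consecutive bins of
#' `period_days` days anchored at `origin_date`. Bin `k` covers
#' `[origin + k*period, origin + (k+1)*period)`; a sample falling exactly on
#' a bin boundary belongs to the later bin (half-open convention). Bins with
#' no samples are `NA` with `gap_mask` set; the bin index runs without holes
#' from 0 to the last covered bin (or to `n_periods - 1` when given, so that
#' trailing gaps are preserved).
#'
#' @param timestamps `Date` vector of the samples.
#' @param values numeric sample values (`NA` samples are dropped).
#' @param origin_date anchor date of bin 0; no sample may precede it.
#' @param period_days compositing period, days.
#' @param n_periods optional fixed series length in bins.
#' @param source provenance tag, see [chl_timeseries()].
#' @return a [chl_timeseries()].
#' @export
bin_composites <- function(timestamps, values, origin_date, period_days = 5L,
                           n_periods = NULL, source = "custom") {
  keep <- !is.na(values)
  timestamps <- timestamps[keep]
  values <- values[keep]
  if (length(values) == 0) bp_stop("no_samples", "no non-missing samples to composite")
  day <- as.numeric(as.Date(timestamps) - as.Date(origin_date))
  if (any(day < 0)) bp_stop("invalid_argument", "samples precede `origin_date`")
  k <- floor(day / period_days)
  n <- n_periods %||% (max(k) + 1)
  if (max(k) + 1 > n) bp_stop("invalid_argument", "samples beyond `n_periods` bins")
  means <- rep(NA_real_, n)
  agg <- tapply(values, factor(k, levels = 0:(n - 1)), mean)
  means[] <- as.numeric(agg)
  chl_timeseries(means, origin_date, period_days, source = source)
}

#' Fill gaps in a composite series
#'
#' The cumulative-sums-of-anomalies detector requires a gap-free series.
#' Interior gaps are filled by linear interpolation between the nearest
#' observed neighbours (the 1-D linear least-squares limit of grid-based
#' in-painting); leading and trailing gaps are extended with the nearest
#' observed value rather than extrapolated, to avoid manufacturing trends at
#' the series ends. Filled bins are marked in `gap_mask`; filled values are
#' clipped at zero. Idempotent on complete series.
#'
#' @param series a [chl_timeseries()] with at least 2 observed values.
#' @return the filled [chl_timeseries()].
#' @export
fill_gaps <- function(series) {
  v <- series$values
  obs <- !is.na(v)
  if (sum(obs) < 2) bp_stop("series_unfillable", "need >= 2 non-missing values to fill")
  if (all(obs)) return(series)
  filled <- stats::approx(which(obs), v[obs], xout = seq_along(v), rule = 2)$y
  series$values <- pmax(filled, 0)
  series$gap_mask <- series$gap_mask | !obs
  series
}

#' Spearman rank correlation between two composite series
#'
#' Compares two series sharing the same bin grid over the bins where both
#' hold observed (non-interpolated, non-missing) values, with average ranks
#' for ties and a two-sided p-value.
#'
#' @param a,b [chl_timeseries()] objects with identical `origin_date` and
#'   `period_days`.
#' @return list with `rho`, `n` (number of paired bins) and `p`.
#' @export
rank_correlation <- function(a, b) {
  if (a$origin_date != b$origin_date || a$period_days != b$period_days) {
    bp_stop("invalid_argument", "series do not share origin/period")
  }
  n <- min(length(a$values), length(b$values))
  ok <- !a$gap_mask[1:n] & !b$gap_mask[1:n] &
    !is.na(a$values[1:n]) & !is.na(b$values[1:n])
  if (sum(ok) < 3) bp_stop("too_few_pairs", "need >= 3 paired observed bins")
  ct <- suppressWarnings(
    stats::cor.test(a$values[1:n][ok], b$values[1:n][ok], method = "spearman"))
  list(rho = unname(ct$estimate), n = sum(ok), p = ct$p.value)
}

#' Construct a gridded satellite chlorophyll field
#'
#' Minimal in-memory container for a per-pixel surface chlorophyll product:
#' sorted coordinate vectors plus a `lon x lat x date` array of values with
#' `NA` for missing pixels.
#'
#' @param lon,lat sorted coordinate vectors (degrees, pixel centres).
#' @param dates `Date` vector.
#' @param chl numeric array with dim `c(length(lon), length(lat),
#'   length(dates))`.
#' @return an object of class `satellite_grid`.
#' @export
satellite_grid <- function(lon, lat, dates, chl) {
  if (!all(dim(chl) == c(length(lon), length(lat), length(dates)))) {
    bp_stop("invalid_grid", "`chl` dimensions must be lon x lat x date")
  }
  if (is.unsorted(lon, strictly = TRUE) || is.unsorted(lat, strictly = TRUE)) {
    bp_stop("invalid_grid", "`lon` and `lat` must be strictly increasing")
  }
  structure(list(lon = lon, lat = lat, dates = as.Date(dates), chl = chl),
            class = "satellite_grid")
}

#' Match one float observation to its satellite pixel window
#'
#' Locates the grid pixel nearest to the float position (nearest latitude and
#' longitude independently; an exact midpoint ties toward the
#' smaller-coordinate pixel), takes that pixel plus its western and eastern
#' longitudinal neighbours at the same latitude, and averages the available
#' values.
#'
#' @param timestamp `Date` of the float observation; the grid must hold that
#'   date.
#' @param lon,lat float position, decimal degrees.
#' @param grid a [satellite_grid()].
#' @return a `matchup_record` list: `timestamp`, `float_lon`, `float_lat`,
#'   `center_pixel_lon`, `center_pixel_lat`, `window_values` (length 3, `NA`
#'   where missing or off-grid) and `matched_value` (mean of available
#'   values; `NA` if the whole window is missing).
#' @export
satellite_matchup <- function(timestamp, lon, lat, grid) {
  it <- match(as.Date(timestamp), grid$dates)
  if (is.na(it)) bp_stop("no_temporal_match", "grid does not cover the float date")
  nearest <- function(coords, x) {
    d <- abs(coords - x)
    # coords sorted ascending, so the first minimum ties west/south; the
    # tolerance absorbs floating-point representation of exact midpoints
    which(d <= min(d) + 1e-9)[1]
  }
  ix <- nearest(grid$lon, lon)
  iy <- nearest(grid$lat, lat)
  win <- rep(NA_real_, 3)
  for (j in -1:1) {
    if (ix + j >= 1 && ix + j <= length(grid$lon)) {
      win[j + 2] <- grid$chl[ix + j, iy, it]
    }
  }
  matched <- if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
  structure(list(timestamp = as.Date(timestamp), float_lon = lon,
                 float_lat = lat, center_pixel_lon = grid$lon[ix],
                 center_pixel_lat = grid$lat[iy], window_values = win,
                 matched_value = matched),
            class = "matchup_record")
}
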