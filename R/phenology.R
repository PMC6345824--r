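#' Phenology threshold criterion
#'
#' The growth-period threshold is the median of the composite series plus 5%,
#' read multiplicatively (`median * 1.05`) following the threshold-criterion
#' convention of the bloom-phenology literature. An additive reading
#' (`median + 0.05` in the series' own units) is available as a switch.
#'
#' @param series a [chl_timeseries()] (complete, see [fill_gaps()]), or a
#'   bare numeric vector.
#' @param rule `"relative"` (default, median x 1.05) or `"absolute"`
#'   (median + 0.05).
#' @return the threshold, in the units of the series.
#' @export
compute_threshold <- function(series, rule = c("relative", "absolute")) {
  rule <- match.arg(rule)
  v <- if (inherits(series, "chl_timeseries")) series$values else as.numeric(series)
  if (length(v) == 0) bp_stop("invalid_series", "empty series")
  if (any(is.na(v))) bp_stop("incomplete_series", "series has missing values; fill gaps first")
  m <- stats::median(v)
  if (rule == "relative") m * 1.05 else m + 0.05
}

#' Anomalies, cumulative sums and their gradient
#'
#' Anomalies are the series minus the threshold criterion; their cumulative
#' sum rises while chlorophyll sits above the threshold and falls while below
#' it, so sign changes of the gradient of the cumulative sum mark the
#' transitions. Because the gradient is taken as the first difference (with
#' the first element kept as the first anomaly), it telescopes back to the
#' anomaly series exactly — the identity the change-point detector rests on.
#'
#' @param series a [chl_timeseries()] or numeric vector, complete.
#' @param threshold the threshold criterion, see [compute_threshold()].
#' @return list with `anomalies`, `cumsum` and `gradient` (identical to
#'   `anomalies` by the telescoping identity).
#' @export
anomaly_cumsum <- function(series, threshold) {
  v <- if (inherits(series, "chl_timeseries")) series$values else as.numeric(series)
  if (any(is.na(v))) bp_stop("incomplete_series", "series has missing values; fill gaps first")
  anomalies <- v - threshold
  cs <- cumsum(anomalies)
  gradient <- c(cs[1], diff(cs))
  list(anomalies = anomalies, cumsum = cs, gradient = gradient)
}

#' Detect bloom phenology metrics
#'
#' Cumulative-sums-of-anomalies change-point detection on a complete
#' composite chlorophyll series. The growth peak is the series maximum (first
#' occurrence on ties). Initiation is the composite period in which the
#' series first rises above the threshold criterion — the first positive
#' gradient of the cumulative sum — within the above-threshold excursion that
#' contains the peak; termination is the first period after the peak in which
#' the gradient turns negative (the series falls below the threshold).
#' Duration is the number of composite periods between initiation and
#' termination. Anomalies exactly zero are neither a rise nor a fall.
#'
#' Indices are 0-based bin indices on the series' own grid (bin `k` starts at
#' `origin_date + k * period_days`), so dates and index differences are pure
#' bin arithmetic.
#'
#' Flags: `no_initiation` (nothing exceeds the threshold), `no_termination`
#' (no negative gradient after the peak), `initiation_at_start` (series
#' already above threshold in bin 0), `multiple_growth_periods` (more than
#' one above-threshold excursion; metrics describe the one holding the global
#' peak).
#'
#' @param series a complete [chl_timeseries()] of at least 3 bins.
#' @param threshold optional externally supplied threshold; default
#'   [compute_threshold()] with `threshold_rule`.
#' @param threshold_rule passed to [compute_threshold()].
#' @return an object of class `phenology_metrics`: `threshold`,
#'   `initiation_index`, `peak_index`, `termination_index` (0-based, `NA`
#'   when undetected), the corresponding `*_date`s, `duration_periods`,
#'   `flags`, and the diagnostic `anomalies`, `cumsum`, `gradient` vectors.
#' @export
detect_metrics <- function(series, threshold = NULL,
                           threshold_rule = c("relative", "absolute")) {
  if (!inherits(series, "chl_timeseries")) {
    bp_stop("invalid_argument", "`series` must be a chl_timeseries")
  }
  v <- series$values
  if (length(v) < 3) bp_stop("invalid_series", "need >= 3 bins")
  if (any(is.na(v))) bp_stop("incomplete_series", "series has missing values; fill gaps first")
  thr <- threshold %||% compute_threshold(series, match.arg(threshold_rule))
  d <- anomaly_cumsum(series, thr)
  an <- d$anomalies
  flags <- character()
  init <- peak <- term <- NA_integer_

  if (!any(an > 0)) {
    flags <- c(flags, "no_initiation", "no_termination")
  } else {
    peak <- which.max(v)  # first occurrence on ties
    pos_runs <- rle(an > 0)
    run_end <- cumsum(pos_runs$lengths)
    run_start <- run_end - pos_runs$lengths + 1
    if (sum(pos_runs$values) > 1) flags <- c(flags, "multiple_growth_periods")
    r <- which(pos_runs$values & run_start <= peak & run_end >= peak)
    init <- run_start[r]
    if (init == 1) flags <- c(flags, "initiation_at_start")
    after <- which(seq_along(an) > peak & an < 0)
    if (length(after) == 0) {
      flags <- c(flags, "no_termination")
    } else {
      term <- after[1]
    }
  }

  to0 <- function(i) if (is.na(i)) NA_integer_ else as.integer(i - 1L)
  idx_date <- function(i0) {
    if (is.na(i0)) as.Date(NA) else series$origin_date + i0 * series$period_days
  }
  out <- list(
    threshold = thr,
    initiation_index = to0(init), peak_index = to0(peak),
    termination_index = to0(term),
    initiation_date = idx_date(to0(init)),
    peak_date = idx_date(to0(peak)),
    termination_date = idx_date(to0(term)),
    duration_periods = if (is.na(init) || is.na(term)) NA_integer_ else
      as.integer(term - init),
    anomalies = d$anomalies, cumsum = d$cumsum, gradient = d$gradient,
    flags = flags,
    origin_date = series$origin_date, period_days = series$period_days,
    source = series$source)
  class(out) <- "phenology_metrics"
  out
}

#' @export
print.phenology_metrics <- function(x, ...) {
  fmt <- function(i, d) if (is.na(i)) "--" else sprintf("bin %d (%s)", i, format(d))
  cat(sprintf("<phenology_metrics %s> threshold %.4g\n", x$source, x$threshold))
  cat("  initiation :", fmt(x$initiation_index, x$initiation_date), "\n")
  cat("  peak       :", fmt(x$peak_index, x$peak_date), "\n")
  cat("  termination:", fmt(x$termination_index, x$termination_date), "\n")
  cat("  duration   :",
      if (is.na(x$duration_periods)) "--" else
        sprintf("%d periods of %d days", x$duration_periods, x$period_days), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Plot the cumulative-sum diagnostics of a detection
#'
#' Two stacked panels: the composite series with its threshold and detected
#' timings, and the gradient of the cumulative sums of anomalies whose sign
#' changes define them.
#'
#' @param x a `phenology_metrics` object.
#' @param series the [chl_timeseries()] it was computed from.
#' @param ... passed to `plot`.
#' @export
plot.phenology_metrics <- function(x, series, ...) {
  dates <- bin_dates(series)
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(dates, series$values, type = "l", ylab = "Chl-a", xlab = "", ...)
  graphics::abline(h = x$threshold, col = "grey50", lty = 2)
  for (d in c(x$initiation_date, x$termination_date)) {
    if (!is.na(d)) graphics::abline(v = d, col = "darkgreen")
  }
  if (!is.na(x$peak_date)) graphics::abline(v = x$peak_date, col = "red", lty = 3)
  plot(dates, x$gradient, type = "h",
       ylab = "gradient of cumulative anomaly sum", xlab = "")
  graphics::abline(h = 0, col = "grey50")
  invisible(x)
}
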