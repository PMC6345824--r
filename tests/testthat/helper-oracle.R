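# Independent brute-force phenology scan: walks the raw series against the
# threshold directly (no anomalies, no cumulative sums, no rle), so it shares
# no code path with detect_metrics.
oracle_detect <- function(values, threshold) {
  above <- values > threshold
  if (!any(above)) {
    return(list(initiation = NA_integer_, peak = NA_integer_,
                termination = NA_integer_,
                flags = c("no_initiation", "no_termination")))
  }
  flags <- character()
  peak <- 1L
  for (i in seq_along(values)) if (values[i] > values[peak]) peak <- i
  init <- peak
  while (init > 1L && above[init - 1L]) init <- init - 1L
  term <- NA_integer_
  j <- peak + 1L
  while (j <= length(values)) {
    if (values[j] < threshold) { term <- j; break }
    j <- j + 1L
  }
  # count distinct above-threshold excursions
  n_runs <- 0L
  prev <- FALSE
  for (a in above) {
    if (a && !prev) n_runs <- n_runs + 1L
    prev <- a
  }
  if (n_runs > 1L) flags <- c(flags, "multiple_growth_periods")
  if (init == 1L) flags <- c(flags, "initiation_at_start")
  if (is.na(term)) flags <- c(flags, "no_termination")
  list(initiation = init - 1L, peak = peak - 1L,
       termination = if (is.na(term)) NA_integer_ else term - 1L,
       flags = flags)
}

# a random composite series shaped like an annual chlorophyll cycle:
# low background with one or more elevated windows plus noise
random_series <- function(n = 73) {
  v <- rep(stats::runif(1, 0.05, 0.2), n)
  for (k in seq_len(sample(0:3, 1))) {
    w <- sort(sample(n, 2))
    v[w[1]:w[2]] <- v[w[1]:w[2]] + stats::runif(1, 0, 0.6)
  }
  pmax(v * (1 + stats::rnorm(n, 0, 0.1)), 0)
}

# quick profile builder for closed-form tests
make_profile <- function(depth, ..., timestamp = as.Date("2016-01-01")) {
  vertical_profile(profile_id = "T1", timestamp = timestamp, depth = depth, ...)
}

# a fast scenario for pipeline-level tests: coarse depth grid, bloom window
# scaled to the series length on composite boundaries, otherwise the default
# study conditions
fast_scenario <- function(n_days = 365, bloom_start_day = NULL,
                          bloom_end_day = NULL, ...) {
  if (is.null(bloom_end_day)) {
    bloom_end_day <- min(n_days, max(2, 5 * round(n_days * 0.5 / 5)))
  }
  if (is.null(bloom_start_day)) {
    bloom_start_day <- max(0, min(bloom_end_day - 1, 5 * round(n_days * 0.25 / 5)))
  }
  synthetic_scenario(depth_grid = seq(1, 1000, by = 5), n_days = n_days,
                     bloom_start_day = bloom_start_day,
                     bloom_end_day = bloom_end_day, ...)
}
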