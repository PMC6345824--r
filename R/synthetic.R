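#' Define a synthetic float/satellite scenario
#'
#' Parameterises a coupled synthetic experiment: an annual cycle in which a
#' subsurface chlorophyll maximum (SCM) sits at 75-100 m during stratified
#' seasons, is eroded during a deep-mixing "bloom" window in which surface
#' chlorophyll is enhanced, while the mixed layer deepens across a pycnocline
#' density step and PAR attenuates exponentially. The planted quantities are
#' returned alongside the generated observations so recovery can be tested.
#'
#' Days are counted from zero: day 0 is `start_date` and the bloom window is
#' the half-open interval `[bloom_start_day, bloom_end_day)`. This aligns
#' bloom transitions with composite bins anchored at `start_date` whenever
#' the planted days are multiples of the compositing period.
#'
#' Schedules (`scm_depth_schedule`, `scm_amplitude_schedule`, `mld_schedule`)
#' are vectorised functions of day-of-series. The defaults emulate a tropical
#' annual cycle: SCM at 75 m deepening to 100 m after the growth period with
#' amplitude 0.35 mg m^-3 outside the bloom window and 0 inside (erosion by
#' mixing); mixed layer 30 m in stratified seasons, deepening smoothly to
#' 200 m at the height of winter convection.
#'
#' @param start_date first day of the series (`Date`).
#' @param n_days series length in days.
#' @param profile_interval_days days between float profiles (the emulated
#'   float surfaced every 1-10 days; default 1).
#' @param depth_grid sampling depths, m, strictly increasing, all positive.
#' @param bloom_start_day,bloom_end_day planted growth-period window,
#'   `0 <= start < end <= n_days` (half-open).
#' @param surface_background_chl,bloom_surface_chl surface mixed-layer
#'   chlorophyll plateau outside/inside the bloom window, mg m^-3.
#' @param scm_depth_schedule,scm_amplitude_schedule,mld_schedule functions
#'   day -> metres / mg m^-3 / metres; `NULL` selects the defaults above.
#' @param scm_sigma Gaussian half-width of the SCM, m.
#' @param pycnocline_delta_sigma density step across the base of the mixed
#'   layer, kg m^-3.
#' @param kd_background diffuse attenuation coefficient for PAR, m^-1.
#' @param par0 surface PAR, umol photons m^-2 s^-1 (only the 1% ratio
#'   matters to the euphotic depth, so a single fixed value is used).
#' @param dark_offset fluorometer dark signal added to every chl sample,
#'   mg m^-3.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   observation noise (0 = noise-free).
#' @param gap_fraction fraction of satellite matchup windows that are fully
#'   missing, in `[0, 1]`.
#' @param npq_depression fractional daytime depression of fluorescence above
#'   the quench depth, in `[0, 1]`.
#' @param quench_depth depth (m) above which NPQ acts, within the mixed
#'   layer.
#' @param lon,lat nominal float position, decimal degrees.
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @return an object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(start_date = as.Date("2015-09-30"),
                               n_days = 365L,
                               profile_interval_days = 1,
                               depth_grid = seq(1, 1000, by = 1),
                               bloom_start_day = 90L,
                               bloom_end_day = 185L,
                               surface_background_chl = 0.1,
                               bloom_surface_chl = 0.5,
                               scm_depth_schedule = NULL,
                               scm_sigma = 15,
                               scm_amplitude_schedule = NULL,
                               mld_schedule = NULL,
                               pycnocline_delta_sigma = 0.5,
                               kd_background = 0.05,
                               par0 = 1500,
                               dark_offset = 0.02,
                               noise_cv = 0.1,
                               gap_fraction = 0.1,
                               npq_depression = 0.3,
                               quench_depth = 15,
                               lon = 34.5, lat = 27.0,
                               seed = 1L) {
  sc <- list(start_date = as.Date(start_date), n_days = as.integer(n_days),
             profile_interval_days = profile_interval_days,
             depth_grid = as.numeric(depth_grid),
             bloom_start_day = as.integer(bloom_start_day),
             bloom_end_day = as.integer(bloom_end_day),
             surface_background_chl = surface_background_chl,
             bloom_surface_chl = bloom_surface_chl,
             scm_depth_schedule = scm_depth_schedule,
             scm_sigma = scm_sigma,
             scm_amplitude_schedule = scm_amplitude_schedule,
             mld_schedule = mld_schedule,
             pycnocline_delta_sigma = pycnocline_delta_sigma,
             kd_background = kd_background, par0 = par0,
             dark_offset = dark_offset, noise_cv = noise_cv,
             gap_fraction = gap_fraction, npq_depression = npq_depression,
             quench_depth = quench_depth, lon = lon, lat = lat,
             seed = as.integer(seed),
             schedules_custom = !all(vapply(
               list(scm_depth_schedule, scm_amplitude_schedule, mld_schedule),
               is.null, TRUE)))
  class(sc) <- "synthetic_scenario"
  validate_scenario(sc)
}

validate_scenario <- function(sc) {
  fail <- function(field, why) {
    bp_stop("invalid_scenario", sprintf("invalid scenario field `%s`: %s", field, why))
  }
  if (sc$n_days < 1) fail("n_days", "must be >= 1")
  if (!(sc$profile_interval_days > 0)) fail("profile_interval_days", "must be > 0")
  z <- sc$depth_grid
  if (length(z) < 2 || any(diff(z) <= 0)) fail("depth_grid", "must be strictly increasing")
  if (any(z <= 0)) fail("depth_grid", "depths must be positive")
  if (!(sc$bloom_start_day < sc$bloom_end_day)) {
    fail("bloom_start_day", "must satisfy bloom_start_day < bloom_end_day")
  }
  if (sc$bloom_end_day > sc$n_days) fail("bloom_end_day", "must be <= n_days")
  if (sc$bloom_start_day < 0) fail("bloom_start_day", "must be >= 0")
  for (f in c("surface_background_chl", "bloom_surface_chl", "scm_sigma",
              "pycnocline_delta_sigma", "kd_background", "par0",
              "dark_offset", "noise_cv")) {
    if (!is.numeric(sc[[f]]) || sc[[f]] < 0) fail(f, "must be >= 0")
  }
  for (f in c("gap_fraction", "npq_depression")) {
    if (!is.numeric(sc[[f]]) || sc[[f]] < 0 || sc[[f]] > 1) fail(f, "must be in [0, 1]")
  }
  if (is.null(sc$scm_depth_schedule)) {
    b1 <- sc$bloom_end_day
    sc$scm_depth_schedule <- function(day) 75 + 25 * ramp01((day - b1) / 60)
  }
  if (is.null(sc$scm_amplitude_schedule)) {
    b0 <- sc$bloom_start_day; b1 <- sc$bloom_end_day
    sc$scm_amplitude_schedule <- function(day) {
      ifelse(day >= b0 & day < b1, 0, 0.35)
    }
  }
  if (is.null(sc$mld_schedule)) {
    b0 <- sc$bloom_start_day; b1 <- sc$bloom_end_day
    sc$mld_schedule <- function(day) {
      inside <- day >= b0 & day < b1
      30 + ifelse(inside, 170 * sin(pi * (day - b0) / (b1 - b0)), 0)
    }
  }
  sc
}

# Noise-free "truth" chlorophyll field at depths z on day-of-series `day`:
# mixed-layer plateau (tapering linearly to zero over 10 m below the MLD)
# plus a Gaussian SCM. No dark offset, no NPQ: those are instrument effects.
truth_chl <- function(sc, day, z) {
  s <- if (day >= sc$bloom_start_day && day < sc$bloom_end_day) {
    sc$bloom_surface_chl
  } else sc$surface_background_chl
  m <- sc$mld_schedule(day)
  taper <- 1 - ramp01((z - m) / 10)
  a <- sc$scm_amplitude_schedule(day)
  zs <- sc$scm_depth_schedule(day)
  s * taper + a * exp(-(z - zs)^2 / (2 * sc$scm_sigma^2))
}

truth_density <- function(sc, day, z) {
  m <- sc$mld_schedule(day)
  delta <- sc$pycnocline_delta_sigma
  # Two-layer profile with the pycnocline step smoothed linearly over 2 m,
  # plus a weak deep stratification so N^2 stays positive below it. The ramp
  # is offset so the 0.03 kg m^-3 threshold above the 10 m reference is
  # crossed exactly at the scheduled MLD in the continuous field; sampling
  # then bounds the detected MLD within one grid step of the schedule.
  z0 <- m - 2 * 0.03 / delta
  1026 + delta * ramp01((z - z0) / 2) + 5e-4 * pmax(z - (z0 + 3), 0)
}

# lognormal multiplicative noise with unit mean and the requested CV
lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic series of float profiles
#'
#' Evaluates the scenario's closed-form fields on the depth grid, one profile
#' per sampling day: chlorophyll fluorescence (truth field, depressed by NPQ
#' above the quench depth, plus the dark offset, times lognormal noise),
#' a two-layer density profile with the pycnocline step at the scheduled MLD,
#' exponentially attenuating PAR, and mixed-layer-homogeneous temperature,
#' salinity and dissolved-oxygen analogues. Deterministic given the scenario
#' seed; the caller's RNG state is left untouched.
#'
#' @param scenario a [synthetic_scenario()].
#' @return a list with `profiles` (list of [vertical_profile()]) and `truth`
#'   (a `truth_record` list: `days`, `dates`, `true_initiation_day`,
#'   `true_termination_day`, `true_mld_by_day`, `true_zeu_by_day`,
#'   `true_scm_depth_by_day` (`NA` while the SCM is eroded),
#'   `true_surface_chl_by_day` — the truth field averaged over the first
#'   optical depth, i.e. what a perfect satellite would report).
#' @export
generate_profile_series <- function(scenario) {
  sc <- validate_scenario(scenario)
  days <- seq(0, sc$n_days - 1, by = sc$profile_interval_days)
  z <- sc$depth_grid
  zeu <- log(100) / sc$kd_background
  # the truth surface layer uses the same convention as the profile module:
  # the 1% light level is referenced to the shallowest sampled PAR, so the
  # satellite truth and a perfectly corrected float profile see one layer
  fod <- (z[1] + zeu) / 4.6
  with_seed(sc$seed, {
    profiles <- vector("list", length(days))
    true_mld <- true_scm <- true_surf <- numeric(length(days))
    for (i in seq_along(days)) {
      d <- days[i]
      m <- sc$mld_schedule(d)
      chl_true <- truth_chl(sc, d, z)
      fluor <- chl_true
      if (sc$npq_depression > 0) {
        quench <- z < min(sc$quench_depth, m)
        fluor[quench] <- fluor[quench] * (1 - sc$npq_depression)
      }
      fluor <- (fluor + sc$dark_offset) * lnoise(length(z), sc$noise_cv)
      dens <- truth_density(sc, d, z)
      par <- sc$par0 * exp(-sc$kd_background * z)
      ramp <- ramp01((z - m) / 30)
      temp <- 27 - 5.5 * ramp
      do <- 205 - 45 * ramp
      profiles[[i]] <- vertical_profile(
        profile_id = sprintf("SYN%04d", i),
        timestamp = sc$start_date + d,
        lon = sc$lon, lat = sc$lat,
        depth = z, pressure = z,
        temperature = temp, salinity = rep(39.5, length(z)),
        density = dens, chl = fluor, do = do, par = par,
        bbp700 = 5e-4 + 1e-3 * chl_true)
      true_mld[i] <- m
      amp <- sc$scm_amplitude_schedule(d)
      true_scm[i] <- if (amp > 0) sc$scm_depth_schedule(d) else NA_real_
      # same trapezoidal surface-layer rule the profile module applies
      true_surf[i] <- trap_integral(z, chl_true, z[1], fod) / (fod - z[1])
    }
    truth <- structure(list(
      days = days, dates = sc$start_date + days,
      true_initiation_day = sc$bloom_start_day,
      true_termination_day = sc$bloom_end_day,
      true_mld_by_day = true_mld,
      true_zeu_by_day = rep(zeu, length(days)),
      true_scm_depth_by_day = true_scm,
      true_surface_chl_by_day = true_surf), class = "truth_record")
    list(profiles = profiles, truth = truth)
  })
}

#' Generate the coupled synthetic satellite series
#'
#' For each float profile date, a 3-pixel longitudinal matchup window whose
#' noise-free mean equals the truth chlorophyll averaged over the first
#' optical depth on that day (the same surface-layer rule the float pipeline
#' applies), with independent lognormal noise per pixel. A fraction
#' `gap_fraction` of windows is fully missing — the emulated cloud/coverage
#' gaps. Deterministic given the scenario seed and independent of the RNG
#' stream used for the profiles.
#'
#' @param scenario a [synthetic_scenario()].
#' @param series the result of [generate_profile_series()] for the same
#'   scenario (its truth record supplies the noise-free surface values).
#' @return a data.frame of class `satellite_series` with columns `date`,
#'   `lon`, `lat`, `pixel_west`, `pixel_center`, `pixel_east` (mg m^-3; all
#'   `NA` for missing windows).
#' @export
generate_satellite_series <- function(scenario, series) {
  sc <- validate_scenario(scenario)
  truth <- series$truth
  n <- length(truth$days)
  with_seed(sc$seed + 1L, {
    win <- matrix(rep(truth$true_surface_chl_by_day, each = 3), nrow = n,
                  ncol = 3, byrow = TRUE)
    win <- win * matrix(lnoise(3 * n, sc$noise_cv), nrow = n)
    n_gap <- floor(sc$gap_fraction * n)
    if (n_gap > 0) win[sample.int(n, n_gap), ] <- NA_real_
    out <- data.frame(date = truth$dates, lon = sc$lon, lat = sc$lat,
                      pixel_west = win[, 1], pixel_center = win[, 2],
                      pixel_east = win[, 3])
    class(out) <- c("satellite_series", "data.frame")
    out
  })
}

#' Matchup values of a satellite series
#'
#' Mean of the available pixels in each 3-pixel window; `NA` where the whole
#' window is missing.
#'
#' @param sat a `satellite_series` data.frame.
#' @return numeric vector of matched values, one per date.
#' @export
matchup_values <- function(sat) {
  m <- rowMeans(as.matrix(sat[, c("pixel_west", "pixel_center", "pixel_east")]),
                na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  m
}
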