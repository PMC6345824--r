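test_that("dark offset removal subtracts the deep median and clips at zero", {
  z <- seq(1, 1000, by = 1)
  chl <- ifelse(z < 100, 0.5, 0.05)
  p <- make_profile(z, chl = chl)
  out <- correct_dark_offset(p)
  expect_equal(attr(out, "dark_offset"), 0.05)
  expect_equal(out$chl[z >= 900], rep(0, sum(z >= 900)))
  expect_equal(out$chl[z < 100], rep(0.45, sum(z < 100)))

  # identically-zero profile is unchanged
  p0 <- make_profile(z, chl = rep(0, length(z)))
  expect_equal(correct_dark_offset(p0)$chl, rep(0, length(z)))

  # never increases chl anywhere
  expect_true(all(out$chl <= p$chl))

  # too few deep samples: skipped with warning, offset recorded absent
  shallow <- make_profile(1:100, chl = rep(0.3, 100))
  expect_warning(res <- correct_dark_offset(shallow), class = "too_few_deep_samples")
  expect_identical(res$chl, shallow$chl)
  expect_true(is.na(attr(res, "dark_offset")))
})

test_that("planted dark offset is recovered from noise-free synthetic profiles", {
  sc <- synthetic_scenario(noise_cv = 0, npq_depression = 0, n_days = 5,
                           bloom_start_day = 1, bloom_end_day = 3,
                           depth_grid = seq(1, 1000, by = 1))
  gen <- generate_profile_series(sc)
  out <- correct_dark_offset(gen$profiles[[1]])
  expect_equal(attr(out, "dark_offset"), sc$dark_offset, tolerance = 1e-12)
})

test_that("fluorescence calibration divides by the bias factor and inverts", {
  p <- make_profile(c(5, 10, 20), chl = c(1.0, 0.8, 0.2))
  expect_equal(apply_fluorescence_calibration(p, 2)$chl, c(0.5, 0.4, 0.1))
  expect_equal(apply_fluorescence_calibration(p, 1)$chl, p$chl)
  roundtrip <- apply_fluorescence_calibration(apply_fluorescence_calibration(p, 2), 0.5)
  expect_equal(roundtrip$chl, p$chl)
  expect_error(apply_fluorescence_calibration(p, 0), class = "invalid_argument")
  expect_error(apply_fluorescence_calibration(p, -2), class = "invalid_argument")
})

test_that("NPQ correction extrapolates the mixed-layer maximum upward", {
  p <- make_profile(c(5, 10, 20, 30, 60), chl = c(0.2, 0.3, 0.5, 0.5, 0.1))
  out <- correct_npq(p, mld = 40, is_daytime = TRUE)
  expect_equal(out$chl, c(0.5, 0.5, 0.5, 0.5, 0.1))

  # monotonically decreasing chl: the mixed-layer max is at the surface
  q <- make_profile(c(5, 10, 20, 30), chl = c(0.5, 0.4, 0.3, 0.2))
  expect_equal(correct_npq(q, mld = 30)$chl, q$chl)

  # night-time profiles are untouched
  expect_equal(correct_npq(p, mld = 40, is_daytime = FALSE)$chl, p$chl)

  # missing MLD: skipped with warning
  expect_warning(res <- correct_npq(p, mld = NA), class = "npq_no_mld")
  expect_equal(res$chl, p$chl)
})

test_that("NPQ correction never decreases chlorophyll at any depth", {
  set.seed(11)
  for (i in 1:50) {
    z <- sort(sample(1:200, 30))
    chl <- stats::runif(30, 0, 1)
    p <- make_profile(z, chl = chl)
    out <- correct_npq(p, mld = stats::runif(1, 10, 150))
    expect_true(all(out$chl >= chl - 1e-15))
  }
})

test_that("oxygen gain correction is a pure multiplier", {
  p <- make_profile(c(5, 50), do = c(100, 200))
  expect_equal(correct_oxygen(p, 1.06)$do, c(106, 212))
  expect_equal(correct_oxygen(p, 1)$do, p$do)
})

test_that("euphotic depth matches the closed form for exponential PAR", {
  z <- seq(0, 300, by = 1)
  for (kd in c(0.03, 0.05, 0.1)) {
    p <- make_profile(z, par = 1000 * exp(-kd * z))
    expect_equal(euphotic_depth(p), log(100) / kd, tolerance = 1e-6)
  }
  # the two spec'd closed-form cases
  p1 <- make_profile(z, par = 1000 * exp(-0.1 * z))
  expect_equal(euphotic_depth(p1), 46.0517, tolerance = 0.05 / 46)
  p2 <- make_profile(z, par = 1000 * exp(-0.04605 * z))
  expect_equal(euphotic_depth(p2), 100, tolerance = 1e-3)
})

test_that("euphotic depth errors when PAR never reaches 1%", {
  p <- make_profile(seq(0, 100, 5), par = rep(800, 21))
  expect_error(euphotic_depth(p), class = "zeu_below_profile")
  expect_error(euphotic_depth(make_profile(c(0, 10), par = c(0, 0))),
               class = "invalid_par")
})

test_that("first optical depth is the euphotic depth over 4.6", {
  expect_equal(first_optical_depth(46.0), 10.0)
  expect_equal(first_optical_depth(4.6), 1.0)
  expect_equal(first_optical_depth(92.0), 20.0)
  expect_error(first_optical_depth(0), class = "invalid_argument")
  expect_error(first_optical_depth(-5), class = "invalid_argument")
})

test_that("surface chlorophyll is the trapezoidal mean over the optical layer", {
  z <- seq(0, 50, by = 1)
  expect_equal(surface_chl(make_profile(z, chl = rep(0.3, length(z))), 10), 0.3)

  # linear ramp 0.4 at 0 m to 0.0 at 20 m, layer 0-10 m: mean 0.3
  zr <- seq(0, 20, by = 1)
  expect_equal(surface_chl(make_profile(zr, chl = 0.4 * (1 - zr / 20)), 10), 0.3)

  # single sample shallower than the layer bottom: degenerate mean
  expect_equal(surface_chl(make_profile(5, chl = 0.42), 10), 0.42)

  expect_error(surface_chl(make_profile(c(30, 40), chl = c(0.1, 0.1)), 10),
               class = "no_surface_samples")
})

test_that("integrated chlorophyll matches rectangles and the Gaussian closed form", {
  z <- seq(0, 50, by = 1)
  expect_equal(integrated_chl(make_profile(z, chl = rep(0.2, length(z))), 0, 50), 10.0)

  zg <- seq(0, 200, by = 1)
  scm <- 0.35 * exp(-(zg - 90)^2 / (2 * 15^2))
  expect_equal(integrated_chl(make_profile(zg, chl = scm), 0, 200),
               0.35 * 15 * sqrt(2 * pi), tolerance = 0.005)

  deep0 <- make_profile(zg, chl = ifelse(zg < 100, 0.4, 0))
  expect_equal(integrated_chl(deep0, 100, 200), 0)

  expect_error(integrated_chl(make_profile(z, chl = rep(0.2, length(z))), 0, 500),
               class = "profile_too_shallow")
})

test_that("integrated chlorophyll is additive over adjacent intervals", {
  set.seed(7)
  z <- seq(0, 300, by = 2)
  chl <- stats::runif(length(z), 0, 1)
  p <- make_profile(z, chl = chl)
  expect_equal(integrated_chl(p, 0, 300),
               integrated_chl(p, 0, 100) + integrated_chl(p, 100, 300),
               tolerance = 1e-12)
})

test_that("MLD threshold method matches hand-derived cases", {
  # sharp two-layer step at 50 m
  z <- seq(1, 200, by = 1)
  dens <- ifelse(z < 50, 1025.0, 1026.0)
  m <- mld(make_profile(z, density = dens))
  expect_lt(abs(m - 50), 1.0)

  # linear density 1025 + 0.001 z: crossing of sigma_ref + 0.03 at exactly 40 m
  expect_equal(mld(make_profile(z, density = 1025 + 0.001 * z)), 40, tolerance = 1e-9)

  # homogeneous profile: bottom depth with flag
  mh <- mld(make_profile(z, density = rep(1025, length(z))))
  expect_equal(as.numeric(mh), 200)
  expect_identical(attr(mh, "flag"), "mld_at_profile_bottom")

  expect_error(mld(make_profile(c(100, 150), density = c(1025, 1026))),
               class = "no_reference_sample")
})

test_that("MLD is invariant under depth-grid refinement", {
  # piecewise-linear density: mixed to 60 m, then a steady increase; both
  # grids sample the kink so each interpolates the same continuous profile
  sigma_fun <- function(z) 1025 + pmax(z - 60, 0) * 0.02
  zc <- seq(0, 200, by = 10); zf <- seq(0, 200, by = 1)
  coarse <- mld(make_profile(zc, density = sigma_fun(zc)))
  fine <- mld(make_profile(zf, density = sigma_fun(zf)))
  expect_lt(abs(coarse - fine), 0.5)
  expect_equal(as.numeric(fine), 61.5, tolerance = 1e-9)
})

test_that("buoyancy frequency matches (g/rho) * slope for linear stratification", {
  z <- seq(1, 200, by = 1)
  p <- make_profile(z, density = 1025 + 0.01 * z)
  b <- bvf_profile(p)
  expect_length(b$n2, length(z) - 1)
  expect_equal(b$n2, rep(9.81 / 1025 * 0.01, length(z) - 1), tolerance = 0.01)
  expect_equal(b$mid_depths, (z[-1] + z[-length(z)]) / 2)

  # homogeneous: zero everywhere; inversion: negative with flag
  expect_equal(bvf_profile(make_profile(z, density = rep(1026, length(z))))$n2,
               rep(0, length(z) - 1))
  inv <- bvf_profile(make_profile(z, density = 1026 - 0.01 * z))
  expect_true(all(inv$n2 < 0))
  expect_identical(inv$flags, "instability")

  # sigma-convention densities (~25) use an absolute rho in the denominator
  bs <- bvf_profile(make_profile(z, density = 25 + 0.01 * z))
  expect_equal(bs$n2, rep(9.81 / 1025 * 0.01, length(z) - 1), tolerance = 0.01)
})

test_that("EOS-80 surface density reproduces reference check values", {
  # pure water at 5 C and standard seawater (S=35) at 5 C and 25 C,
  # from the Millero & Poisson (1981) polynomial itself evaluated externally
  expect_equal(sw_sigma0(5, 0), -0.03325, tolerance = 1e-3)
  expect_gt(sw_sigma0(5, 35), sw_sigma0(25, 35))   # colder is denser
  expect_gt(sw_sigma0(25, 39.5), sw_sigma0(25, 35)) # saltier is denser
  expect_equal(sw_sigma0(25, 35), 23.343, tolerance = 1e-2)
})

test_that("derive_all recovers planted scalars and honours missing inputs", {
  sc <- synthetic_scenario(noise_cv = 0, npq_depression = 0, n_days = 3,
                           bloom_start_day = 1, bloom_end_day = 2,
                           kd_background = log(100) / 100,  # Zeu 100 m
                           mld_schedule = function(day) rep(60, length(day)),
                           depth_grid = seq(1, 1000, by = 1))
  gen <- generate_profile_series(sc)
  # npq off: the quenching stand-in extrapolates the mixed-layer maximum,
  # which here sits on the SCM shoulder and would bias chl_surf upward
  d <- derive_all(gen$profiles[[1]], list(calibration_factor = 1, npq = FALSE))
  expect_equal(d$zeu, 100, tolerance = 0.02)
  expect_equal(d$fod, d$zeu / 4.6, tolerance = 1e-12)
  expect_equal(d$mld, 60, tolerance = 1.0)
  expect_equal(d$chl_surf, 0.1, tolerance = 0.01)

  # profile lacking PAR: zeu/fod/chl_surf absent, mld still computed
  p <- gen$profiles[[2]]
  p$par <- NULL
  d2 <- derive_all(p, list(calibration_factor = 1))
  expect_true(is.na(d2$zeu) && is.na(d2$fod) && is.na(d2$chl_surf))
  expect_false(is.na(d2$mld))
  expect_true(any(grepl("par absent", d2$provenance)))

  # corrections are applied exactly once even if pre-applied
  pre <- correct_dark_offset(gen$profiles[[3]])
  d3a <- derive_all(pre, list(calibration_factor = 1))
  d3b <- derive_all(gen$profiles[[3]], list(calibration_factor = 1))
  expect_equal(d3a$chl_surf, d3b$chl_surf, tolerance = 1e-12)
})
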