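test_that("scenario validation names the offending field", {
  expect_error(synthetic_scenario(bloom_start_day = 200, bloom_end_day = 100),
               "bloom_start_day", class = "invalid_scenario")
  expect_error(synthetic_scenario(bloom_end_day = 400),
               "bloom_end_day", class = "invalid_scenario")
  expect_error(synthetic_scenario(depth_grid = c(10, 5, 1)),
               "depth_grid", class = "invalid_scenario")
  expect_error(synthetic_scenario(gap_fraction = 1.5),
               "gap_fraction", class = "invalid_scenario")
  expect_error(synthetic_scenario(noise_cv = -0.1),
               "noise_cv", class = "invalid_scenario")
})

test_that("noise-free profiles equal the closed-form field", {
  # no SCM, no NPQ: chl at 5 m is exactly the plateau plus the dark offset
  sc <- synthetic_scenario(noise_cv = 0, npq_depression = 0,
                           scm_amplitude_schedule = function(day) 0 * day,
                           bloom_start_day = 100, bloom_end_day = 200,
                           surface_background_chl = 0.1, bloom_surface_chl = 0.5,
                           depth_grid = seq(1, 1000, by = 1))
  gen <- generate_profile_series(sc)
  i5 <- which(sc$depth_grid == 5)
  in_bloom <- gen$truth$days >= 100 & gen$truth$days < 200
  chl5 <- vapply(gen$profiles, function(p) p$chl[i5], 0)
  expect_equal(chl5[in_bloom], rep(0.5 + sc$dark_offset, sum(in_bloom)))
  expect_equal(chl5[!in_bloom], rep(0.1 + sc$dark_offset, sum(!in_bloom)))
})

test_that("the SCM appears at the scheduled depth with the scheduled amplitude", {
  sc <- synthetic_scenario(noise_cv = 0, npq_depression = 0,
                           scm_depth_schedule = function(day) rep(90, length(day)),
                           scm_amplitude_schedule = function(day) rep(0.35, length(day)),
                           scm_sigma = 15,
                           bloom_start_day = 3, bloom_end_day = 6,
                           depth_grid = seq(1, 1000, by = 1), n_days = 10)
  gen <- generate_profile_series(sc)
  p <- gen$profiles[[1]]
  deep <- p$depth > 50
  expect_equal(p$depth[deep][which.max(p$chl[deep])], 90)
  expect_equal(max(p$chl[deep]), 0.35 + sc$dark_offset, tolerance = 1e-9)
})

test_that("generation is bit-identical for the same seed and differs across seeds", {
  sc <- fast_scenario(n_days = 30, seed = 7)
  a <- generate_profile_series(sc)
  b <- generate_profile_series(sc)
  expect_identical(a, b)
  sat_a <- generate_satellite_series(sc, a)
  expect_identical(sat_a, generate_satellite_series(sc, b))
  sc2 <- fast_scenario(n_days = 30, seed = 8)
  expect_false(identical(generate_profile_series(sc2)$profiles[[1]]$chl,
                         a$profiles[[1]]$chl))
})

test_that("generation leaves the caller's RNG stream untouched", {
  set.seed(123)
  before <- stats::runif(3)
  set.seed(123)
  invisible(generate_profile_series(fast_scenario(n_days = 5)))
  expect_identical(stats::runif(3), before)
})

test_that("noise-free satellite windows equal the truth surface-layer mean", {
  sc <- fast_scenario(noise_cv = 0, gap_fraction = 0, npq_depression = 0, n_days = 40)
  gen <- generate_profile_series(sc)
  sat <- generate_satellite_series(sc, gen)
  expect_equal(matchup_values(sat), gen$truth$true_surface_chl_by_day)
  expect_equal(sat$pixel_west, sat$pixel_east)
})

test_that("gap fraction plants the exact deterministic number of missing windows", {
  sc <- fast_scenario(gap_fraction = 0.2, n_days = 100, seed = 3)
  gen <- generate_profile_series(sc)
  sat1 <- generate_satellite_series(sc, gen)
  sat2 <- generate_satellite_series(sc, gen)
  missing1 <- which(is.na(matchup_values(sat1)))
  expect_length(missing1, 20)
  expect_identical(missing1, which(is.na(matchup_values(sat2))))

  # gap_fraction = 1: every window missing, downstream series is all-gap
  sc_all <- fast_scenario(gap_fraction = 1, n_days = 20)
  sat_all <- generate_satellite_series(sc_all, generate_profile_series(sc_all))
  expect_true(all(is.na(matchup_values(sat_all))))
})

test_that("planted MLD is recovered from noise-free density at every date", {
  sc <- synthetic_scenario(noise_cv = 0, npq_depression = 0,
                           profile_interval_days = 10,
                           depth_grid = seq(1, 1000, by = 1))
  gen <- generate_profile_series(sc)
  step <- 1
  for (i in seq_along(gen$profiles)) {
    m <- mld(gen$profiles[[i]])
    expect_lt(abs(as.numeric(m) - gen$truth$true_mld_by_day[i]), step + 1e-9)
  }
})

test_that("planted euphotic depth is recovered from noise-free PAR", {
  for (kd in c(0.03, 0.05, 0.1)) {
    sc <- synthetic_scenario(kd_background = kd, n_days = 3,
                             bloom_start_day = 1, bloom_end_day = 2,
                             depth_grid = seq(1, 1000, by = 1))
    gen <- generate_profile_series(sc)
    zeu <- euphotic_depth(gen$profiles[[1]])
    expect_lt(abs(zeu - log(100) / kd), 1 + 1e-9)  # one grid step
  }
})

test_that("raising bloom surface chl raises composites only inside the bloom window", {
  base <- fast_scenario(noise_cv = 0, gap_fraction = 0, npq_depression = 0,
                        bloom_surface_chl = 0.5)
  high <- fast_scenario(noise_cv = 0, gap_fraction = 0, npq_depression = 0,
                        bloom_surface_chl = 0.8)
  surf <- function(sc) {
    gen <- generate_profile_series(sc)
    s <- bin_composites(gen$truth$dates, gen$truth$true_surface_chl_by_day,
                        origin_date = sc$start_date, period_days = 5)
    s$values
  }
  vb <- surf(base); vh <- surf(high)
  in_bloom <- seq_along(vb) - 1 >= base$bloom_start_day / 5 &
    seq_along(vb) - 1 < base$bloom_end_day / 5
  expect_true(all(vh[in_bloom] > vb[in_bloom]))
  expect_equal(vh[!in_bloom], vb[!in_bloom])
})

test_that("scenario and profile fixtures round-trip through CSV and JSON", {
  tmp <- withr::local_tempdir()
  sc <- fast_scenario(n_days = 4, seed = 5)
  gen <- generate_profile_series(sc)

  ppath <- file.path(tmp, "profiles.csv")
  write_profiles_csv(gen$profiles, ppath)
  back <- read_profiles_csv(ppath)
  expect_length(back, 4)
  expect_equal(back[[1]]$chl, gen$profiles[[1]]$chl, tolerance = 1e-9)
  expect_equal(back[[3]]$density, gen$profiles[[3]]$density, tolerance = 1e-9)

  jpath <- file.path(tmp, "scenario.json")
  write_scenario_json(sc, jpath)
  sc2 <- read_scenario_json(jpath)
  expect_equal(sc2$seed, sc$seed)
  expect_equal(sc2$depth_grid, sc$depth_grid)
  expect_identical(generate_profile_series(sc2)$profiles[[2]]$chl,
                   gen$profiles[[2]]$chl)
})
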