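test_that("the hazard follows [S(t) - S(t+1)] / S(t) on exact counts", {
  # survivors 100 -> 90 -> 81, then extinction at t = 3
  dt <- rep(c(1, 2, 3), c(10, 9, 81))
  hz <- hazard_curve(dt)
  expect_equal(hz$S, c(100, 90, 81))
  expect_equal(hz$mu, c(0.10, 0.10, 1.0))
})

test_that("certain death at the first step gives a unit hazard", {
  hz <- hazard_curve(rep(1, 25))
  expect_equal(nrow(hz), 1)
  expect_equal(hz$mu, 1)
})

test_that("censored individuals stay in the risk set and steps past extinction are NA", {
  hz <- hazard_curve(c(1, 1, NA, NA), max_t = 5)
  expect_equal(hz$S, c(4, 2, 2, 2, 2))
  expect_equal(hz$mu, c(0.5, 0, 0, 0, 0))

  hz2 <- hazard_curve(c(1, 1), max_t = 3)
  expect_equal(hz2$S, c(2, 0, 0))
  expect_true(all(is.na(hz2$mu[2:3])))

  expect_error(hazard_curve(numeric(0)), "empty")
  expect_error(hazard_curve(c(NA_real_, NA_real_)), "max_t")
  expect_error(hazard_curve(c(0.5, 2)), "positive integers")
})

test_that("cause-specific hazards follow d_i(t) / S(t) and sum to the all-cause hazard", {
  # S(1) = 200 with 10 intrinsic and 30 co-ageing deaths at t = 1
  dt <- c(rep(1, 40), rep(2, 160))
  cz <- c(rep("intrinsic", 10), rep("coageing", 30), rep("intrinsic", 160))
  hz <- cause_specific_hazards(dt, cz)
  expect_equal(hz$mu_s[1], 0.05)
  expect_equal(hz$mu_c[1], 0.15)
  expect_equal(hz$mu[1], 0.20)
  expect_identical(hz$mu, hz$mu_s + hz$mu_c)

  expect_error(cause_specific_hazards(c(1, 2), c("intrinsic", "accident")),
               "unknown death cause")
})

test_that("additivity holds exactly on a simulated cohort", {
  pars <- ref_params()
  coh <- simulate_cohort(pars$A, pars$B, cohort_size = 300, max_steps = 3000,
                         master_seed = 8)
  dem <- demography(coh)
  ok <- dem$S > 0
  expect_identical(dem$mu[ok], dem$mu_s[ok] + dem$mu_c[ok])
  expect_true(all(is.na(dem$mu[!ok])))
  # both causes actually occur under the reference condition
  expect_true(all(c("intrinsic", "coageing") %in%
                    coh$summary$death_cause[!coh$summary$censored]))
})

test_that("interval mortality generalizes the one-step hazard", {
  expect_equal(interval_mortality(100, 100, 5), 0)
  expect_equal(interval_mortality(100, 81, delta_t = 2), 0.1)
  expect_error(interval_mortality(90, 100), "cannot increase")
  expect_error(interval_mortality(100, 0), "S_tf")
  expect_error(interval_mortality(100, 90, delta_t = 0), "delta_t")

  # delta_t = 1 reduction: identical to the hazard definition on any series
  set.seed(1)
  dt <- sample(1:40, 500, replace = TRUE)
  hz <- hazard_curve(dt)
  keep <- which(hz$S > 0 & dplyr::lead(hz$S, default = 0) >= 0)
  for (t in head(keep, -1)) {
    if (hz$S[t + 1] > 0) {
      expect_identical(interval_mortality(hz$S[t], hz$S[t] - hz$deaths[t], 1),
                       hz$mu[t])
    }
  }
})

test_that("moving-average smoothing is centred with truncated endpoints", {
  x <- c(0, 1, 0, 1, 0)
  expect_identical(smooth_hazard(x, 1), x)
  expect_equal(smooth_hazard(x, 3), c(1 / 2, 1 / 3, 2 / 3, 1 / 3, 1 / 2))
  expect_equal(smooth_hazard(rep(0.3, 10), 5), rep(0.3, 10))
  expect_error(smooth_hazard(x, 2), "odd")
  # NA tail stays NA and does not leak into the defined prefix
  y <- c(0.1, 0.2, 0.3, NA, NA)
  sm <- smooth_hazard(y, 3)
  expect_true(all(is.na(sm[4:5])))
  expect_false(anyNA(sm[1:3]))
})

test_that("bump detection reports max-then-min shapes and ignores monotone series", {
  expect_equal(nrow(detect_bump(1:10, window = 1)), 0)
  expect_false(has_bump(as.numeric(1:10), window = 1))
  expect_equal(nrow(detect_bump(rep(2, 10), window = 1)), 0)

  shape <- c(1, 2, 4, 7, 5, 3, 2, 3, 5, 8)
  ext <- detect_bump(shape, window = 1)
  expect_equal(ext$type, c("max", "min"))
  expect_equal(ext$t, c(4, 7))
  expect_true(has_bump(ext))
  expect_equal(bump_amplitude(ext), 5)

  # rising tail without a preceding max is not a bump
  expect_false(has_bump(c(5, 4, 3, 2, 3, 4, 5), window = 1))
  expect_error(detect_bump(c(1, 2)), "length")
})

test_that("significance guards suppress sampling noise", {
  set.seed(42)
  n <- 200
  S <- round(seq(2000, 900, length.out = n))
  flat <- 0.02
  noisy <- rbinom(n, S, flat) / S
  expect_false(has_bump(detect_bump(noisy, window = 15, S = S,
                                    min_S = 400, se_mult = 6)))
  # a genuine bump an order of magnitude above the noise floor survives
  bumpy <- noisy + 0.05 * exp(-((seq_len(n) - 40) / 12)^2)
  expect_true(has_bump(detect_bump(bumpy, window = 15, S = S,
                                   min_S = 400, se_mult = 6)))
})

test_that("hazard tables round-trip through the delimited format", {
  hz <- hazard_curve(c(1, 2, 2, 3, NA))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hazard_table(hz, path)
  back <- read_hazard_table(path)
  expect_equal(back$S, hz$S)
  expect_equal(back$mu, hz$mu)
})
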