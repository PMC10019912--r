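years_pre <- 1920:1966

test_that("gamma effort curve recovers known parameters from noiseless data", {
  truth <- list(amplitude = 5200, shape = 3.2, scale = 28, onset = 1901)
  hours <- truth$amplitude * stats::dgamma(years_pre - truth$onset,
                                           shape = truth$shape,
                                           scale = truth$scale)
  fit <- fit_effort_curve(years_pre, hours)
  expect_true(fit$converged)
  expect_lt(abs(fit$amplitude / truth$amplitude - 1), 0.01)
  expect_lt(abs(fit$shape / truth$shape - 1), 0.01)
  expect_lt(abs(fit$scale / truth$scale - 1), 0.01)
  expect_lt(abs((fit$onset_year - truth$onset) / truth$onset), 0.01)
  expect_lt(fit$residual_se, 1e-3)

  # prediction at a training year reproduces the observed value
  pr <- predict_effort(fit, 1950)
  expect_equal(pr$fit, hours[years_pre == 1950], tolerance = 1e-4)
})

test_that("gamma curve fitting enforces its preconditions and degeneracies", {
  expect_error(fit_effort_curve(1950:1952, c(3, 4, 5)), "at least 5")
  expect_error(fit_effort_curve(1950:1960, rep(-1, 11)), "positive")
  expect_error(fit_effort_curve(1950:1955, 1:5), "equal length")
  # constant hours: must not crash; either a near-flat fit or a flagged one
  flat <- fit_effort_curve(1940:1960, rep(12, 21))
  expect_s3_class(flat, "gamma_curve_fit")
  if (flat$converged) {
    pr <- predict_effort(flat, 1940:1960)
    expect_lt(max(abs(pr$fit - 12)), 6)
  }
})

test_that("effort predictions carry 2-SE intervals with width 4*SE", {
  hours <- 4000 * stats::dgamma(years_pre - 1900, 3, scale = 30) +
    rep(c(-1, 1), length.out = length(years_pre))
  fit <- fit_effort_curve(years_pre, pmax(hours, 0.5))
  pr <- predict_effort(fit, c(1930, 1950, 1970))
  expect_equal(pr$width, pr$upper - pr$lower, tolerance = 1e-12)
  expect_equal(pr$width, rep(4 * fit$residual_se, 3), tolerance = 1e-12)

  zero_se <- fit
  zero_se$residual_se <- 0
  expect_equal(predict_effort(zero_se, 1950)$width, 0)
})

test_that("loess smoother reproduces linear effort and refuses extrapolation", {
  yrs <- 1968:2018
  hours <- 10 + 0.8 * (yrs - 1968)
  sm <- smooth_effort(yrs, hours, c(1980, 2000))
  expect_equal(sm$fit, 10 + 0.8 * (c(1980, 2000) - 1968), tolerance = 1e-6)

  out <- smooth_effort(yrs, hours, c(1950, 1960))
  expect_identical(nrow(out), 0L)
  expect_identical(attr(out, "deferred"), c(1950, 1960))

  expect_identical(nrow(smooth_effort(yrs, hours, integer())), 0L)
  expect_error(smooth_effort(1970:1975, 1:6, 1972), "at least 10")

  # duplicating one observation moves the prediction by less than its SE
  noisy <- hours + sin(seq_along(yrs))
  base <- smooth_effort(yrs, noisy, 1990)
  dup <- smooth_effort(c(yrs, 1990), c(noisy, noisy[yrs == 1990]), 1990)
  expect_lt(abs(dup$fit - base$fit), max(base$width / 4, 1e-6))
})

test_that("assembled effort series covers every year with correct provenance", {
  yrs <- 1919:2018
  truth <- 5000 * stats::dgamma(yrs - 1900, 3, scale = 30)
  observed <- truth
  observed[yrs < 1940] <- NA            # pre-cutoff gap -> gamma curve
  observed[yrs %in% c(1990, 2005)] <- NA # modern gaps -> smoother
  es <- assemble_effort(yrs, observed)
  expect_identical(nrow(es), length(yrs))
  expect_identical(es$year, yrs)
  # observed entries pass through unchanged with zero width
  obs_idx <- !is.na(observed)
  expect_identical(es$effort[obs_idx], observed[obs_idx])
  expect_true(all(es$width[obs_idx] == 0))
  expect_true(all(es$source[obs_idx] == "observed"))
  expect_true(all(es$source[yrs < 1940] == "gamma"))
  expect_true(all(es$source[yrs %in% c(1990, 2005)] == "smoother"))
  expect_true(all(es$width[!obs_idx] >= 0))
  expect_true(all(es$effort > 0))

  # fully observed circle: identity, all widths zero
  es2 <- assemble_effort(yrs, truth + 0.2)
  expect_identical(es2$effort, truth + 0.2)
  expect_true(all(es2$width == 0))

  # nothing to fit from: the failure names the year
  expect_error(assemble_effort(2001:2006, c(NA, NA, 3, 4, 5, NA)),
               "cannot impute")
})

test_that("panel-level imputation approaches truth as effort noise vanishes", {
  cfg <- simulation_config(n_circles = 5, seed = 31, effort_noise_sd = 0,
                           effort_curve = list(amplitude = 6000, shape = 3,
                                               scale = 30, onset_year = 1900,
                                               amplitude_cv = 0),
                           unsurveyed_prob_pre1967 = 0,
                           unsurveyed_prob_post1967 = 0,
                           missing_prob_pre1967 = 0.5,
                           missing_prob_post1967 = 0.04)
  sim <- simulate_panel(cfg)
  truth <- sim$truth$effort$truth
  panel <- impute_effort(sim$panel)
  expect_false(anyNA(panel$effort))
  was_missing <- is.na(sim$panel$effort)
  big <- was_missing & truth > 1   # skip floor-clipped early-century values
  rel_err <- abs(panel$effort[big] - truth[big]) / truth[big]
  expect_lt(max(rel_err), 0.01)
  # observed entries never altered
  expect_identical(panel$effort[!was_missing], sim$panel$effort[!was_missing])
  expect_true(all(panel$effort_width[!was_missing] == 0))
  expect_true(all(panel$effort_width[was_missing] >= 0))
})
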