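test_that("simulation is reproducible and rejects invalid configurations", {
  cfg <- simulation_config(n_circles = 6, year_start = 1950, year_end = 1990,
                           seed = 33)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a, b)

  expect_error(simulation_config(n_circles = 0), "positive")
  expect_error(simulation_config(year_start = 2000, year_end = 1999),
               "exceed")
  expect_error(simulation_config(missing_prob_pre1967 = 1.4), "0, 1")
})

test_that("covariates are complete, step-wise in time, and degenerate under a single circle", {
  cfg <- simulation_config(n_circles = 12, year_start = 1919,
                           year_end = 2018, seed = 4)
  cov <- generate_covariates(cfg)
  years <- cov$years
  expect_false(anyNA(cov$habitat))
  expect_true(all(cov$habitat >= 0 & cov$developed >= 0 & cov$density >= 0))

  # density configured as decadal steps: exhaustive scan that within-decade
  # values never change
  step_start <- years[1] + 10 * ((years - years[1]) %/% 10)
  for (i in seq_len(nrow(cov$density)))
    for (t in seq_along(years)) {
      anchor <- which(years == step_start[t])
      expect_identical(cov$density[i, t], cov$density[i, anchor])
    }

  cfg1 <- simulation_config(n_circles = 1, seed = 9)
  cov1 <- generate_covariates(cfg1)
  expect_length(cov1$elevation, 1)
  expect_identical(dim(cov1$habitat), c(1L, 100L))
})

test_that("latent dynamics obey the survival/recruitment update and its limits", {
  I <- 40; T <- 12
  covs <- constant_covariates(I, T)

  # omega ~ 1, gamma ~ 0: population frozen at its initial size
  frozen <- generate_latent_dynamics(flat_params(lam0 = log(8), om0 = 30,
                                                 gam0 = -30),
                                     covs, seed = 2)
  expect_true(all(frozen$N == frozen$N[, 1]))

  # omega ~ 0, gamma ~ 0: extinction from year 2 on
  extinct <- generate_latent_dynamics(flat_params(lam0 = log(8), om0 = -30,
                                                  gam0 = -30),
                                      covs, seed = 2)
  expect_true(all(extinct$N[, -1] == 0))

  # conservation invariants on a generic simulation
  lat <- generate_latent_dynamics(default_dmm_params(),
                                  constant_covariates(30, 20), seed = 5)
  expect_true(all(lat$N[, -1] == lat$S[, -1] + lat$R[, -1]))
  expect_true(all(lat$S[, -1] <= lat$N[, -20]))
})

test_that("mean one-step growth matches omega + gamma over many replicate sites", {
  I <- 10000
  covs <- constant_covariates(I, 2)
  om <- 0.7; ga <- 0.25
  lat <- generate_latent_dynamics(flat_params(lam0 = log(20),
                                              om0 = qlogis(om),
                                              gam0 = log(ga)),
                                  covs, seed = 8)
  ok <- lat$N[, 1] > 0
  ratio <- lat$N[ok, 2] / lat$N[ok, 1]
  mc_se <- stats::sd(ratio) / sqrt(sum(ok))
  expect_lt(abs(mean(ratio) - (om + ga)), 3 * mc_se)
})

test_that("recruitment is Poisson-dispersed at fixed parent abundance", {
  I <- 20000
  covs <- constant_covariates(I, 2)
  lat <- generate_latent_dynamics(flat_params(lam0 = log(50), om0 = -30,
                                              gam0 = log(0.3)),
                                  covs, seed = 12)
  at50 <- lat$N[, 1] == 50
  expect_gt(sum(at50), 300)
  r <- lat$R[at50, 2]
  disp <- stats::var(r) / mean(r)
  # var/mean of a Poisson sample: 1 +/- sqrt(2/(n-1)) roughly
  expect_lt(abs(disp - 1), 3 * sqrt(2 / (sum(at50) - 1)))
})

test_that("observation process thins the latent abundance binomially", {
  N <- matrix(100L, 10000, 1)
  lat <- make_latent(N)
  eff <- matrix(20, 10000, 1)
  tmp <- matrix(0, 10000, 1)

  perfect <- generate_observations(lat, eff, tmp, list(fixed_p = 1), seed = 3)
  expect_true(all(perfect$X == N))
  none <- generate_observations(lat, eff, tmp, list(fixed_p = 0), seed = 3)
  expect_true(all(none$X == 0))

  half <- generate_observations(lat, eff, tmp, list(fixed_p = 0.5), seed = 3)
  mc_se <- stats::sd(half$X) / sqrt(length(half$X))
  expect_lt(abs(mean(half$X) - 50), 3 * mc_se)

  # X is missing exactly where the effort table is NA (no survey)
  eff[1:100, 1] <- NA
  masked <- generate_observations(lat, eff, tmp, list(fixed_p = 0.5), seed = 3)
  expect_true(all(is.na(masked$X[1:100])))
  expect_false(anyNA(masked$X[101:10000]))
  expect_true(all(masked$X[101:10000] <= N[101:10000]))
})

test_that("effort generation follows the gamma curve and the masking regime", {
  cfg <- simulation_config(n_circles = 60, seed = 14, effort_noise_sd = 0,
                           effort_curve = list(amplitude = 6000, shape = 3,
                                               scale = 30, onset_year = 1900,
                                               amplitude_cv = 0))
  eff <- generate_effort(cfg)
  years <- eff$years
  expected <- pmax(6000 * stats::dgamma(years - 1900, 3, scale = 30), 0.1)
  for (i in c(1, 30, 60))
    expect_equal(eff$truth[i, !is.na(eff$truth[i, ])],
                 expected[!is.na(eff$truth[i, ])], tolerance = 1e-12)

  # everything pre-1967 masked when the missingness probability is 1
  cfg2 <- simulation_config(n_circles = 10, seed = 15,
                            missing_prob_pre1967 = 1)
  eff2 <- generate_effort(cfg2)
  pre <- eff2$years < 1967
  expect_true(all(is.na(eff2$observed[, pre])))

  # masked fraction among surveyed cells matches the configured probability
  cfg3 <- simulation_config(n_circles = 200, seed = 16,
                            missing_prob_pre1967 = 0.5,
                            missing_prob_post1967 = 0.04)
  eff3 <- generate_effort(cfg3)
  for (era in list(c(TRUE, 0.5), c(FALSE, 0.04))) {
    cols <- (eff3$years < 1967) == era[1]
    surveyed <- eff3$surveyed[, cols]
    masked <- surveyed & !eff3$recorded[, cols]
    n <- sum(surveyed)
    frac <- sum(masked) / n
    expect_lt(abs(frac - era[2]), 3 * sqrt(era[2] * (1 - era[2]) / n))
  }
})

test_that("trend archetypes are exact at zero noise and recoverable under noise", {
  clean <- generate_trend_archetypes(1, length = 80, noise_sd = 0, seed = 1)
  expect_equal(clean$trends, clean$archetypes[clean$labels, ],
               ignore_attr = TRUE)
  expect_identical(tabulate(clean$labels, 4), rep(1L, 4))

  rng <- mean(apply(clean$archetypes, 1, function(r) diff(range(r))))
  noisy <- generate_trend_archetypes(250, length = 80,
                                     noise_sd = 0.1 * rng, seed = 2)
  expect_identical(tabulate(noisy$labels, 4), rep(250L, 4))
  # brute-force nearest-template classification recovers >= 99% of labels
  d <- sapply(seq_len(4), function(k)
    rowSums(sweep(noisy$trends, 2, noisy$archetypes[k, ])^2))
  guess <- apply(d, 1, which.min)
  expect_gte(mean(guess == noisy$labels), 0.99)
})

test_that("study filters drop under-sampled and under-detected circles", {
  T <- 100
  counts <- matrix(NA_integer_, 5, T)
  sampled <- c(10, 29, 30, 31, 100)
  for (i in 1:5) counts[i, seq_len(sampled[i])] <- 5L
  panel <- make_panel(counts, years = 1919:2018)
  out <- apply_study_filters(panel)
  removed <- attr(out, "removed")
  # exactly two circles fall below 30 samplings; a circle sampled exactly
  # 30 times is retained ("fewer than" is strict)
  expect_identical(nrow(removed), 2L)
  expect_setequal(removed$circle, panel$circles[1:2])
  expect_true(all(removed$reason == "insufficient_samplings"))
  expect_length(out$circles, 3)

  # detection filter: a circle with enough samplings but sparse detections
  counts2 <- matrix(0L, 2, T)
  counts2[1, 1:9] <- 1L    # 9 detections < 10
  counts2[2, 1:50] <- 2L
  out2 <- apply_study_filters(make_panel(counts2, years = 1919:2018))
  expect_identical(attr(out2, "removed")$reason, "insufficient_detections")
  expect_length(out2$circles, 1)

  # nothing to remove: output equals input
  full <- make_panel(matrix(3L, 4, 40), years = 1979:2018)
  kept <- apply_study_filters(full)
  expect_identical(kept$counts, full$counts)
  expect_identical(attr(kept, "n_removed"), 0L)

  # empty result warns rather than fails
  tiny <- make_panel(matrix(1L, 2, 5), years = 2014:2018)
  expect_warning(apply_study_filters(tiny), "empty")
})
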