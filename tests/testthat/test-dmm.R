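# Link-scale arithmetic, likelihoods, the exhaustive-marginal oracle, and
# sampler contracts on tiny instances. Full-scale convergence and recovery
# live in test-acceptance.R.

test_that("linear predictors reproduce the link identities", {
  I <- 3; T <- 4
  Z <- array(0, c(I, T, 4))
  eff <- matrix(0, I, T); tmp <- matrix(0, I, T)
  lp <- linear_predictors(flat_params(), Z, eff, tmp)
  expect_equal(lp$Lambda, rep(1, I))
  expect_equal(unname(lp$omega[, 2]), rep(0.5, I))
  expect_equal(unname(lp$gamma[, 2]), rep(1, I))
  expect_true(all(lp$p == 0.5))

  # scalar check: p at effort 1, temp -1 with a = (0, 0.5, -0.5)
  lp2 <- linear_predictors(flat_params(), Z, matrix(1, I, T),
                           matrix(-1, I, T))
  expect_equal(lp2$p[1, 1], stats::plogis(1), tolerance = 1e-12)
  expect_equal(lp2$p[1, 1], 0.7310586, tolerance = 1e-6)

  # p is increasing in effort, decreasing in temperature, with limits 1/0
  effs <- seq(-3, 50, length.out = 30)
  ps <- stats::plogis(0 + 0.5 * effs)
  expect_true(all(diff(ps) > 0))
  lp3 <- linear_predictors(flat_params(), Z, matrix(1e6, I, T), tmp)
  expect_equal(lp3$p[1, 1], 1, tolerance = 1e-9)

  # visibly unstandardized covariates trigger a warning
  Zbad <- array(5, c(I, T, 4))
  Zbad[1, 1, ] <- 5.5
  expect_warning(linear_predictors(flat_params(), Zbad, eff, tmp),
                 "standardized")
})

test_that("complete-data log-likelihood matches term-by-term arithmetic", {
  # 2 sites x 2 years, all quantities <= 5, flat covariates so the rates
  # are pure intercepts
  counts <- rbind(c(2L, 3L), c(1L, 1L))
  panel <- make_panel(counts, effort = matrix(c(10, 20, 30, 40), 2, 2),
                      temp = matrix(c(-2, 0, 1, 3), 2, 2))
  params <- flat_params(lam0 = log(3), om0 = qlogis(0.7), gam0 = log(0.4),
                        alpha = c(0.2, 0.6, -0.4))
  latent <- make_latent(N = rbind(c(4L, 5L), c(2L, 2L)),
                        S = rbind(c(NA, 3L), c(NA, 1L)),
                        R = rbind(c(NA, 2L), c(NA, 1L)))
  ll <- complete_data_loglik(params, latent, panel)

  # independent hand computation of the four densities
  d <- cbctrends:::dmm_model_data(panel)
  p <- stats::plogis(0.2 + 0.6 * d$effort_z + (-0.4) * d$temp_z)
  by_hand <-
    sum(stats::dpois(c(4, 2), 3, log = TRUE)) +
    stats::dbinom(3, 4, 0.7, log = TRUE) +
    stats::dbinom(1, 2, 0.7, log = TRUE) +
    stats::dpois(2, 0.4 * 4, log = TRUE) +
    stats::dpois(1, 0.4 * 2, log = TRUE) +
    sum(stats::dbinom(counts, rbind(c(4, 5), c(2, 2)), p, log = TRUE))
  expect_equal(ll, by_hand, tolerance = 1e-10)

  # support violations give -Inf, not an error
  bad <- latent; bad$N[1, 1] <- 1L  # X = 2 > N = 1
  expect_identical(complete_data_loglik(params, bad, panel), -Inf)
  bad2 <- latent; bad2$S[1, 2] <- 5L; bad2$R[1, 2] <- 0L
  expect_identical(complete_data_loglik(params, bad2, panel), -Inf)
})

test_that("perfect detection collapses the observation term", {
  panel <- make_panel(matrix(3L, 1, 1))
  params <- flat_params(lam0 = log(2), alpha = c(40, 1e-9, -1e-9))
  latent <- make_latent(matrix(3L, 1, 1))
  expect_equal(complete_data_loglik(params, latent, panel),
               stats::dpois(3, 2, log = TRUE), tolerance = 1e-6)
})

test_that("exhaustive marginal likelihood obeys closed forms and truncation limits", {
  params <- flat_params(lam0 = log(2), alpha = c(0, 0.5, -0.5))

  # single site, single year: Poisson thinning, X ~ Pois(Lambda * p)
  for (x in c(0L, 1L, 3L)) {
    panel <- make_panel(matrix(x, 1, 1), effort = matrix(20, 1, 1),
                        temp = matrix(0, 1, 1))
    d <- cbctrends:::dmm_model_data(panel)
    p <- stats::plogis(0 + 0.5 * d$effort_z[1, 1] - 0.5 * d$temp_z[1, 1])
    expect_equal(marginal_loglik_bruteforce(params, panel, n_max = 60),
                 stats::dpois(x, 2 * p, log = TRUE), tolerance = 1e-8)
  }

  # normalization: the implied observation distribution sums to 1
  lls <- sapply(0:30, function(x)
    marginal_loglik_bruteforce(params,
                               make_panel(matrix(x, 1, 1),
                                          effort = matrix(20, 1, 1),
                                          temp = matrix(0, 1, 1)),
                               n_max = 40))
  expect_lt(abs(sum(exp(lls)) - 1), 1e-8)

  # truncation convergence at Lambda = 2
  panel2 <- make_panel(rbind(c(1L, 2L, 1L)), effort = matrix(c(8, 12, 20), 1),
                       temp = matrix(0, 1, 3))
  l20 <- marginal_loglik_bruteforce(params, panel2, n_max = 20)
  l30 <- marginal_loglik_bruteforce(params, panel2, n_max = 30)
  expect_lt(abs(l30 - l20), 1e-10)

  # refuses instances beyond its scope, with the size in the message
  expect_error(marginal_loglik_bruteforce(params,
                                          make_panel(matrix(1L, 4, 2)),
                                          n_max = 10),
               "too large")
})

test_that("the sampler is deterministic given a seed and respects its contracts", {
  set.seed(71)
  counts <- matrix(rpois(8 * 6, 4), 8, 6)
  panel <- make_panel(counts, effort = matrix(runif(48, 5, 40), 8, 6))
  ctrl <- mcmc_control(n_iter = 600, n_burnin = 300, n_chains = 2, thin = 3)
  f1 <- suppressMessages(sample_posterior(panel, ctrl, seed = 9))
  f2 <- suppressMessages(sample_posterior(panel, ctrl, seed = 9))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$N_draws, f2$N_draws)

  # sign constraints hold in every retained draw
  expect_true(all(f1$draws[, "p_effort", ] > 0))
  expect_true(all(f1$draws[, "p_temp", ] < 0))

  # latent invariants hold in every retained draw:
  # N = S + R (t >= 2), S_t <= N_{t-1}, X <= N where surveyed
  I <- 8; T <- 6
  for (ch in 1:2) {
    N <- f1$N_draws[, , ch]; S <- f1$S_draws[, , ch]; R <- f1$R_draws[, , ch]
    cell <- function(m, i, t) m[, i + I * (t - 1)]
    for (t in 2:T) for (i in 1:I) {
      expect_true(all(cell(N, i, t) == cell(S, i, t) + cell(R, i, t)))
      expect_true(all(cell(S, i, t) <= cell(N, i, t - 1)))
    }
    for (t in 1:T) for (i in 1:I)
      expect_true(all(cell(N, i, t) >= counts[i, t]))
  }

  # unknown fixed-coefficient names are rejected
  expect_error(suppressMessages(
    sample_posterior(panel, ctrl, seed = 1, fixed = c(nope = 1))),
    "unknown coefficient")
})

test_that("posterior abundance matches truth under forced perfect detection", {
  set.seed(55)
  cfg <- simulation_config(n_circles = 6, year_start = 2004, year_end = 2018,
                           dmm_params = recovery_dmm_params(), seed = 17,
                           unsurveyed_prob_post1967 = 0,
                           missing_prob_post1967 = 0)
  cov <- generate_covariates(cfg)
  latent <- generate_latent_dynamics(cfg$dmm_params, cov, seed = 18)
  eff <- generate_effort(cfg)
  tmp <- generate_temperature(cfg, cov$latitude)
  obs <- generate_observations(latent, eff$truth, tmp, list(fixed_p = 1),
                               seed = 19)
  panel <- obs_panel(obs$X, eff$observed, tmp, cov, years = cov$years)
  fit <- suppressMessages(sample_posterior(
    panel, mcmc_control(n_iter = 3000, n_burnin = 1500, n_chains = 2,
                        thin = 5),
    seed = 20,
    fixed = c(p_0 = 15, p_effort = 1e-6, p_temp = -1e-6)))
  nm <- apply(fit$N_draws, 2, mean)
  truthN <- as.vector(latent$N)
  rel <- abs(nm - truthN) / pmax(truthN, 1)
  expect_lt(max(rel), 0.05)
})

test_that("Gelman-Rubin behaves at its analytic anchor points", {
  # two identical chains: exactly 1
  x <- matrix(rnorm(2000), 1000, 2)
  a <- array(c(x[, 1], x[, 2], x[, 1], x[, 2]), c(1000, 2, 2),
             dimnames = list(NULL, c("a", "b"), NULL))
  rh <- gelman_rubin(a)
  expect_equal(unname(rh), c(1, 1), tolerance = 1e-12)

  # i.i.d. chains from one distribution: just above 1
  set.seed(2)
  b <- array(rnorm(10000 * 3), c(10000, 1, 3),
             dimnames = list(NULL, "a", NULL))
  expect_lt(gelman_rubin(b), 1.01)

  # chains centred 10 apart: far above the convergence cut
  cc <- array(c(rnorm(5000), rnorm(5000, 10)), c(5000, 1, 2),
              dimnames = list(NULL, "a", NULL))
  expect_gt(gelman_rubin(cc), 5)

  expect_error(gelman_rubin(array(rnorm(100), c(100, 1, 1))), "2 chains")
  expect_error(gelman_rubin(array(rnorm(10), c(5, 1, 2))), ">= 10")
})

test_that("Gelman-Rubin agrees with the reference implementation's ordering", {
  skip_if_not_installed("coda")
  set.seed(4)
  sims <- array(c(rnorm(3000, 0, 1), rnorm(3000, 0.15, 1.1)),
                c(3000, 1, 2), dimnames = list(NULL, "a", NULL))
  ours <- gelman_rubin(sims)
  theirs <- coda::gelman.diag(coda::mcmc.list(
    coda::mcmc(sims[, 1, 1]), coda::mcmc(sims[, 1, 2])))$psrf[1, 1]
  # same between/within signal; our form omits the (n-1)/n deflation and
  # df correction, so agreement is to a few per mille at this n
  expect_lt(abs(ours - theirs), 0.01)
})

test_that("abundance summaries are exact quantile/mean computations", {
  # hand-built fit object: 2 circles x 2 years, known draws
  n_draw <- 400
  set.seed(9)
  Nd <- array(0, c(n_draw, 4, 2))
  for (cell in 1:4) Nd[, cell, ] <- matrix(rpois(n_draw * 2, 10 * cell),
                                           n_draw, 2)
  fit <- structure(list(
    draws = array(0, c(n_draw, 18, 2),
                  dimnames = list(NULL, cbctrends:::par_names_dmm(), NULL)),
    N_draws = Nd, circles = c("c1", "c2"), years = c(2001L, 2002L),
    control = mcmc_control(n_iter = 20, n_burnin = 10)),
    class = "dmm_fit")
  sm <- summarize_abundance(fit)
  pooled <- rbind(Nd[, , 1], Nd[, , 2])
  expect_equal(sm$cells$mean, colMeans(pooled), tolerance = 1e-12)
  expect_equal(sm$cells$lo95,
               apply(pooled, 2, quantile, 0.025, names = FALSE))
  expect_equal(sm$cells$hi95,
               apply(pooled, 2, quantile, 0.975, names = FALSE))
  expect_true(all(sm$cells$lo95 <= sm$cells$mean &
                    sm$cells$mean <= sm$cells$hi95))
  # region-wide mean at year t is the mean of the per-circle means
  mu <- matrix(colMeans(pooled), 2, 2)
  expect_equal(sm$yearly$mean_abundance, colMeans(mu), tolerance = 1e-12)

  # constant draws: degenerate interval
  fit$N_draws[] <- 7
  sm2 <- summarize_abundance(fit)
  expect_true(all(sm2$cells$mean == 7 & sm2$cells$lo95 == 7 &
                    sm2$cells$hi95 == 7))
})
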