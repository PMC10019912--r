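#' Configuration for the synthetic CBC-like panel generator
#'
#' Bundles every tunable of the simulator: panel dimensions, the gamma-shaped
#' effort growth curve and its missingness regime, the survey-occurrence
#' regime, the latent population-dynamics parameters, the temperature model
#' and covariate step structure.
#'
#' Effort history is emulated as a scaled gamma-density curve in calendar
#' time (slow start around the survey's founding, growth through the 20th
#' century), with multiplicative lognormal noise. Whether a circle was
#' surveyed at all, and whether party hours were recorded given a survey took
#' place, are governed by separate pre/post-1967 probabilities: early decades
#' of the count have many surveys whose effort was simply never written down.
#'
#' @param n_circles number of circles (sites).
#' @param year_start,year_end first and last calendar year of the panel.
#' @param effort_curve list with `amplitude` (party-hour scale), `shape`,
#'   `scale` (years), `onset_year` (calendar year the curve starts), and
#'   `amplitude_cv` -- lognormal coefficient of variation of per-circle
#'   amplitudes.
#' @param effort_noise_sd sdlog of the multiplicative lognormal noise on the
#'   effort curve (0 = deterministic curve).
#' @param missing_prob_pre1967,missing_prob_post1967 probability that party
#'   hours went unrecorded at a surveyed circle-year before/after 1967.
#' @param unsurveyed_prob_pre1967,unsurveyed_prob_post1967 probability that a
#'   circle skipped the count entirely in a given year.
#' @param dmm_params a [dmm_params()] object driving the latent dynamics and
#'   detection.
#' @param temp_model list with `base_mean` (deg C at the southern edge),
#'   `lat_gradient` (deg C lost across the latitudinal span) and `sd`
#'   (between-survey sd).
#' @param habitat_step,density_step years between changes of the land-cover
#'   and human-density covariates (density is decadal, mirroring census-style
#'   sources; values are carried forward between steps).
#' @param seed integer RNG seed; a fixed seed makes every generated object
#'   byte-identical across runs.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_circles = 20,
                              year_start = 1919, year_end = 2018,
                              effort_curve = list(amplitude = 6000, shape = 3,
                                                  scale = 30,
                                                  onset_year = 1900,
                                                  amplitude_cv = 0.3),
                              effort_noise_sd = 0.15,
                              missing_prob_pre1967 = 0.5,
                              missing_prob_post1967 = 0.04,
                              unsurveyed_prob_pre1967 = 0.3,
                              unsurveyed_prob_post1967 = 0.05,
                              dmm_params = century_dmm_params(),
                              temp_model = list(base_mean = 0,
                                                lat_gradient = 12, sd = 4),
                              habitat_step = 5, density_step = 10,
                              seed = 1L) {
  if (!is.numeric(n_circles) || n_circles < 1)
    stop("n_circles must be a positive integer", call. = FALSE)
  if (year_end <= year_start)
    stop("year_end must exceed year_start", call. = FALSE)
  probs <- c(missing_prob_pre1967, missing_prob_post1967,
             unsurveyed_prob_pre1967, unsurveyed_prob_post1967)
  if (any(probs < 0 | probs > 1))
    stop("missingness/survey probabilities must lie in `[0, 1]`", call. = FALSE)
  cfg <- list(n_circles = as.integer(n_circles),
              year_start = as.integer(year_start),
              year_end = as.integer(year_end),
              effort_curve = effort_curve,
              effort_noise_sd = effort_noise_sd,
              missing_prob_pre1967 = missing_prob_pre1967,
              missing_prob_post1967 = missing_prob_post1967,
              unsurveyed_prob_pre1967 = unsurveyed_prob_pre1967,
              unsurveyed_prob_post1967 = unsurveyed_prob_post1967,
              dmm_params = dmm_params, temp_model = temp_model,
              habitat_step = as.integer(habitat_step),
              density_step = as.integer(density_step),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Generate site covariates
#'
#' Draws static elevation and step-wise time-varying covariates (preferred
#' habitat area, developed-land area, human population density) for every
#' circle-year. Habitat and developed area change only at `habitat_step`-year
#' boundaries; density only at `density_step`-year (decadal) boundaries; all
#' values are carried forward between steps, mirroring land-cover products
#' compiled every few years. Habitat tends to shrink and developed area and
#' density to grow over the century, each by a multiplicative random walk.
#'
#' A synthetic latitude index in `[0, 1]` is attached for the temperature
#' model; it does not enter the population model.
#'
#' @param config a [simulation_config()].
#' @return A covariate list as used by [obs_panel()], plus `latitude`.
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  I <- config$n_circles
  years <- config$year_start:config$year_end
  T <- length(years)
  elevation <- stats::runif(I, 0, 2500)
  latitude <- stats::runif(I, 0, 1)

  step_walk <- function(start, step_years, drift, sd) {
    # multiplicative random walk sampled at step boundaries, carried forward
    m <- matrix(NA_real_, I, T)
    steps <- unique(c(1L, which((years - years[1]) %% step_years == 0L)))
    vals <- start
    for (t in seq_len(T)) {
      if (t %in% steps && t > 1L)
        vals <- vals * exp(stats::rnorm(I, drift, sd))
      m[, t] <- vals
    }
    m
  }
  habitat <- step_walk(stats::runif(I, 50, 400), config$habitat_step,
                       drift = -0.01, sd = 0.05)
  developed <- step_walk(stats::runif(I, 5, 50), config$habitat_step,
                         drift = 0.02, sd = 0.05)
  density <- step_walk(stats::rlnorm(I, log(30), 0.8), config$density_step,
                       drift = 0.08, sd = 0.05)
  list(elevation = elevation, habitat = habitat, developed = developed,
       density = density, latitude = latitude, years = years)
}

#' Generate sampling effort with survey and recording masks
#'
#' Per-circle mean effort follows a scaled gamma-density curve over calendar
#' years, multiplied by lognormal noise (keeping party hours strictly
#' positive). Each circle-year is independently surveyed or not, and -- given
#' a survey -- party hours are recorded or not, with separate pre/post-1967
#' probabilities.
#'
#' @param config a [simulation_config()].
#' @return A list with matrices `truth` (actual party hours; `NA` where no
#'   survey took place), `observed` (party hours visible to the analyst:
#'   additionally `NA` where unrecorded), logical `surveyed` and `recorded`
#'   masks, and the `years` vector.
#' @export
generate_effort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  I <- config$n_circles
  years <- config$year_start:config$year_end
  T <- length(years)
  ec <- config$effort_curve
  amp <- ec$amplitude * stats::rlnorm(I, -ec$amplitude_cv^2 / 2,
                                      ec$amplitude_cv)
  curve <- outer(amp, stats::dgamma(years - ec$onset_year, shape = ec$shape,
                                    scale = ec$scale))
  noise <- if (config$effort_noise_sd > 0)
    matrix(stats::rlnorm(I * T, -config$effort_noise_sd^2 / 2,
                         config$effort_noise_sd), I, T)
  else matrix(1, I, T)
  truth <- pmax(curve * noise, 0.1)

  pre <- matrix(rep(years < 1967, each = I), I, T)
  p_skip <- ifelse(pre, config$unsurveyed_prob_pre1967,
                   config$unsurveyed_prob_post1967)
  p_miss <- ifelse(pre, config$missing_prob_pre1967,
                   config$missing_prob_post1967)
  surveyed <- matrix(stats::runif(I * T), I, T) >= p_skip
  recorded <- surveyed & (matrix(stats::runif(I * T), I, T) >= p_miss)
  truth[!surveyed] <- NA_real_
  observed <- truth
  observed[!recorded] <- NA_real_
  list(truth = truth, observed = observed, surveyed = surveyed,
       recorded = recorded, years = years)
}

#' Generate per-survey minimum temperature
#'
#' Minimum temperature on count day, drawn from a circle-specific normal
#' whose mean falls linearly with the circle's latitude index (colder
#' farther north). Temperature exists for every circle-year (weather-station
#' records do not depend on the survey).
#'
#' @param config a [simulation_config()].
#' @param latitude per-circle latitude index in `[0, 1]`
#'   (from [generate_covariates()]).
#' @return An I x T numeric matrix of minimum temperatures (deg C).
#' @export
generate_temperature <- function(config, latitude) {
  stopifnot(inherits(config, "sim_config"),
            length(latitude) == config$n_circles)
  set.seed(config$seed + 2L)
  tm <- config$temp_model
  T <- config$year_end - config$year_start + 1L
  mu <- tm$base_mean - tm$lat_gradient * latitude
  matrix(stats::rnorm(config$n_circles * T, rep(mu, T), tm$sd),
         config$n_circles, T)
}

#' Simulate latent population dynamics
#'
#' Draws the latent abundance process of the open-population model:
#' initial abundance `N[i,1] ~ Poisson(Lambda_i)`, survivors
#' `S[i,t] ~ Binomial(N[i,t-1], omega_it)`, recruits
#' `R[i,t] ~ Poisson(gamma_it * N[i,t-1])`, and `N[i,t] = S[i,t] + R[i,t]`.
#' Rates come from [linear_predictors()] applied to internally standardized
#' covariates.
#'
#' @param params a [dmm_params()] object.
#' @param covariates covariate list from [generate_covariates()].
#' @param seed integer RNG seed.
#' @return A list of class `latent_state` with integer matrices `N`, `S`,
#'   `R` (columns are years; `S`/`R` are `NA` in the first year) and the
#'   rate matrices used.
#' @export
generate_latent_dynamics <- function(params, covariates, seed = 1L) {
  stopifnot(inherits(params, "dmm_params"))
  set.seed(seed)
  Z <- standardize_covariates(covariates)
  I <- dim(Z)[1]; T <- dim(Z)[2]
  lp <- linear_predictors(params, Z,
                          effort = matrix(0, I, T), temp = matrix(0, I, T))
  N <- S <- R <- matrix(NA_integer_, I, T)
  N[, 1] <- stats::rpois(I, lp$Lambda)
  for (t in seq_len(T)[-1]) {
    S[, t] <- stats::rbinom(I, N[, t - 1], lp$omega[, t])
    R[, t] <- stats::rpois(I, lp$gamma[, t] * N[, t - 1])
    N[, t] <- S[, t] + R[, t]
  }
  structure(list(N = N, S = S, R = R, omega = lp$omega, gamma = lp$gamma,
                 Lambda = lp$Lambda),
            class = "latent_state")
}

#' Simulate observed counts from latent abundance
#'
#' Binomial thinning of the latent abundance: where a survey took place
#' (effort not `NA`), `X[i,t] ~ Binomial(N[i,t], p_it)` with detection
#' `p = plogis(a0 + a_e * effort_z + a_m * temp_z)` on standardized effort
#' and temperature; `X` is `NA` where effort is `NA` (no survey).
#'
#' @param latent a `latent_state` from [generate_latent_dynamics()].
#' @param effort I x T matrix of true party hours (`NA` = no survey).
#' @param temp I x T matrix of minimum temperatures.
#' @param detection_params list with `alpha = c(a0, a_e, a_m)` (`a_e > 0`,
#'   `a_m < 0`) or `fixed_p` -- a constant detection probability overriding
#'   the covariate model (useful for perfect-detection checks).
#' @param seed integer RNG seed.
#' @return A list with the integer count matrix `X` and the detection
#'   matrix `p`.
#' @export
generate_observations <- function(latent, effort, temp, detection_params,
                                  seed = 1L) {
  stopifnot(inherits(latent, "latent_state"),
            all(dim(effort) == dim(latent$N)),
            all(dim(temp) == dim(latent$N)))
  set.seed(seed)
  I <- nrow(latent$N); T <- ncol(latent$N)
  if (!is.null(detection_params$fixed_p)) {
    p <- matrix(detection_params$fixed_p, I, T)
  } else {
    a <- detection_params$alpha
    stopifnot(length(a) == 3)
    ez <- standardize_matrix(effort)
    tz <- standardize_matrix(temp)
    p <- stats::plogis(a[1] + a[2] * ez + a[3] * tz)
  }
  X <- matrix(NA_integer_, I, T)
  idx <- which(!is.na(effort))
  X[idx] <- stats::rbinom(length(idx), latent$N[idx], p[idx])
  list(X = X, p = p)
}

#' Simulate a complete CBC-like observation panel
#'
#' End-to-end generator: covariates, effort (with survey/recording masks),
#' temperature, latent dynamics and observed counts, assembled into an
#' [obs_panel()] as the analyst would see it (effort `NA` where unrecorded).
#'
#' @param config a [simulation_config()].
#' @return A list with `panel` (the [obs_panel()]) and `truth` -- a list
#'   holding the latent state, true effort, masks, detection matrix and
#'   generating parameters, for recovery checks.
#' @export
simulate_panel <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  cov <- generate_covariates(config)
  eff <- generate_effort(config)
  temp <- generate_temperature(config, cov$latitude)
  latent <- generate_latent_dynamics(config$dmm_params, cov,
                                     seed = config$seed + 3L)
  obs <- generate_observations(latent, eff$truth, temp,
                               list(alpha = config$dmm_params$alpha),
                               seed = config$seed + 4L)
  panel <- obs_panel(obs$X, eff$observed, temp, cov,
                     years = cov$years,
                     circles = sprintf("circle_%03d", seq_len(config$n_circles)))
  list(panel = panel,
       truth = list(latent = latent, effort = eff, temp = temp,
                    detection = obs$p, covariates = cov,
                    params = config$dmm_params, config = config))
}

#' Generate planted trend archetypes
#'
#' Draws standardized trend curves from four smooth archetypes -- steady
#' decline (steepest early), steady increase, increase-then-decline, and
#' flat-then-late-increase -- plus i.i.d. Gaussian noise, returning the true
#' class labels. These are the four canonical century-scale trajectory
#' shapes the clustering stage is meant to recover.
#'
#' @param n_per_class rows per archetype (>= 1).
#' @param length number of time points per curve.
#' @param noise_sd sd of additive noise (archetypes are standardized to
#'   mean 0, sd 1, so 0.1 is 10% of a unit-scale signal).
#' @param seed integer RNG seed.
#' @return A list with `trends` (4 * n_per_class x length matrix), integer
#'   `labels` (1..4), and `archetypes` (4 x length noiseless matrix).
#' @export
generate_trend_archetypes <- function(n_per_class, length = 100,
                                      noise_sd = 0.1, seed = 1L) {
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  set.seed(seed)
  x <- seq(0, 1, length.out = length)
  shapes <- rbind(
    exp(-2.5 * x),                        # steady decline, fastest early
    stats::plogis(6 * (x - 0.5)),         # steady increase
    exp(-((x - 0.4) / 0.25)^2),           # increase then decline
    pmax(0, x - 0.55)^1.5)                # flat, then late increase
  arch <- t(apply(shapes, 1, function(r) (r - mean(r)) / stats::sd(r)))
  lab <- rep(seq_len(4), each = n_per_class)
  trends <- arch[lab, , drop = FALSE] +
    matrix(stats::rnorm(4 * n_per_class * length, 0, noise_sd),
           4 * n_per_class, length)
  list(trends = trends, labels = lab, archetypes = arch)
}

# Standardize a matrix over its non-NA entries; a constant (or singleton)
# matrix maps to zeros rather than 0/0 (internal).
standardize_matrix <- function(m) {
  v <- m[!is.na(m)]
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) s <- 1
  (m - mean(v)) / s
}

# Build the standardized I x T x 4 covariate array the model operates on:
# each covariate centred and scaled over all circle-years. Human density is
# log-transformed first -- it is strongly right-skewed and enters the
# linear predictors on the log scale (internal).
standardize_covariates <- function(covariates) {
  I <- length(covariates$elevation)
  T <- ncol(covariates$habitat)
  z <- function(m) as.vector(scale(as.vector(m)))
  arr <- array(NA_real_, c(I, T, 4),
               dimnames = list(NULL, NULL,
                               c("elevation", "habitat", "developed",
                                 "density")))
  elev <- matrix(covariates$elevation, I, T)
  arr[, , 1] <- z(elev)
  arr[, , 2] <- z(covariates$habitat)
  arr[, , 3] <- z(covariates$developed)
  arr[, , 4] <- z(log(pmax(covariates$density, 1e-6)))
  # a covariate constant over all circle-years carries no information;
  # map it to exact zeros rather than 0/0
  for (j in 1:4) if (anyNA(arr[, , j])) arr[, , j] <- 0
  arr
}
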