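#' MCMC configuration for the open-population sampler
#'
#' Two presets are provided: `"desk"` (3 chains x 20,000 iterations, 10,000
#' burn-in, thin 10) sized for interactive work and the test suite, and
#' `"production"` (100,000 iterations, 80,000 burn-in) for a full-length
#' run.
#'
#' @param n_iter total iterations per chain.
#' @param n_burnin burn-in iterations discarded (adaptation of proposal
#'   scales happens only here).
#' @param n_chains number of chains (>= 2 needed for convergence
#'   diagnostics).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param preset `"desk"` or `"production"`; explicit arguments override the
#'   preset.
#' @param effort_error how the effort prediction-interval width maps to the
#'   measurement-error sd on the detection covariate: `"quarter"`
#'   (sd = width/4, i.e. the 2-SE half-width back-transformed to one SE;
#'   the default), `"half"` (width/2) or `"full"` (width).
#' @param latent_jump maximum step of the integer random walk on the latent
#'   counts.
#' @param latent_sweeps latent-state update sweeps per iteration (more
#'   sweeps buy faster mixing of the abundance-detection ridge per
#'   iteration at proportional cost).
#' @param joint_reps attempts of the adaptive joint coefficient proposal
#'   per iteration.
#' @param prior_sd sd of the Normal(0, prior_sd^2) coefficient priors
#'   (half-normal for the sign-constrained detection slopes).
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(n_iter = NULL, n_burnin = NULL, n_chains = 3,
                         thin = 10, preset = c("desk", "production"),
                         effort_error = c("quarter", "half", "full"),
                         latent_jump = 3, latent_sweeps = 2, joint_reps = 6,
                         prior_sd = 10) {
  preset <- match.arg(preset)
  effort_error <- match.arg(effort_error)
  if (is.null(n_iter))
    n_iter <- if (preset == "production") 100000L else 20000L
  if (is.null(n_burnin))
    n_burnin <- if (preset == "production") 80000L else 10000L
  stopifnot(n_burnin < n_iter, n_chains >= 1, thin >= 1)
  structure(list(n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin),
                 n_chains = as.integer(n_chains), thin = as.integer(thin),
                 preset = preset, effort_error = effort_error,
                 latent_jump = as.integer(latent_jump),
                 latent_sweeps = as.integer(latent_sweeps),
                 joint_reps = as.integer(joint_reps),
                 prior_sd = prior_sd),
            class = "mcmc_control")
}

#' Fit the single-visit open-population model by MCMC
#'
#' Metropolis-within-Gibbs sampling over the latent integer abundances
#' (per-site random-walk proposals on initial abundance, survivors and
#' recruits that respect `N_t = S_t + R_t` and `S_t <= N_{t-1}`), the 18
#' regression coefficients (adaptive univariate random walks plus a jointly
#' adapted multivariate proposal, both tuned during burn-in only), and --
#' where the effort prediction-interval width is positive -- a latent
#' detection-effort covariate with a normal measurement model centred at
#' the imputed value. Coefficient priors are Normal(0, `prior_sd`^2);
#' the detection effort and temperature slopes are restricted to the
#' positive and negative half-lines respectively.
#'
#' Chains are initialized over-dispersed: coefficients start at 0 (the
#' sign-constrained slopes just inside their half-lines) plus a
#' chain-specific jitter; latent abundance starts cell-wise near twice
#' the observed count, with unsurveyed years interpolated from their
#' neighbours. Given `seed`, output is reproducible.
#'
#' @param panel an [obs_panel()] whose effort is complete at surveyed
#'   circle-years (see [impute_effort()]).
#' @param control an [mcmc_control()].
#' @param seed integer seed; chain `c` uses `seed + c - 1`.
#' @param fixed optional named numeric vector of coefficients to hold fixed
#'   (names from the `lam_*`, `om_*`, `gam_*`, `p_*` scheme; see
#'   [dmm_params()]); used e.g. to profile a single free parameter against
#'   the exhaustive-likelihood oracle.
#' @param init optional [dmm_params()] giving common starting values.
#' @return An object of class `dmm_fit`: `draws` (kept x 18 x chains
#'   array), `N_draws`, `S_draws`, `R_draws` (kept x circle-years x
#'   chains), acceptance rates, the model data scaling, and the control
#'   used.
#' @export
sample_posterior <- function(panel, control = mcmc_control(), seed = 1L,
                             fixed = NULL, init = NULL) {
  stopifnot(inherits(panel, "obs_panel"), inherits(control, "mcmc_control"))
  d <- dmm_model_data(panel)
  if (any(rowSums(d$surveyed) == 0))
    stop("some circles have no surveyed years at all; apply_study_filters() ",
         "should remove them before fitting", call. = FALSE)

  width_factor <- switch(control$effort_error,
                         quarter = 0.25, half = 0.5, full = 1)
  sdE <- d$width_z * width_factor
  message("effort measurement-error sd = interval width x ", width_factor,
          " (", control$effort_error, ")")

  nm <- par_names_dmm()
  theta0 <- stats::setNames(rep(0, 18), nm)
  theta0["p_effort"] <- 0.1
  theta0["p_temp"] <- -0.1
  if (!is.null(init)) theta0[] <- flatten_params(init)
  update_mask <- rep(TRUE, 18)
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), nm)
    if (length(bad))
      stop("unknown coefficient names in `fixed`: ",
           paste(bad, collapse = ", "), call. = FALSE)
    theta0[names(fixed)] <- fixed
    update_mask[match(names(fixed), nm)] <- FALSE
  }
  if (theta0["p_effort"] <= 0 || theta0["p_temp"] >= 0) {
    warning("initial detection slopes violate sign constraints; corrected",
            call. = FALSE)
    theta0["p_effort"] <- abs(theta0["p_effort"]) + 0.05
    theta0["p_temp"] <- -abs(theta0["p_temp"]) - 0.05
  }

  X <- d$X
  X[is.na(X)] <- -1L
  storage.mode(X) <- "integer"
  # cell-wise start at roughly twice the observed count (detection ~ 0.5),
  # carrying neighbouring values across unsurveyed years; a flat start at
  # the site maximum pins early-year detection near zero on growing sites
  # and can trap all chains in a low-detection mode
  N_init <- t(apply(d$X, 1, function(v) {
    if (all(is.na(v))) return(rep(1L, length(v)))
    filled <- stats::approx(seq_along(v), v, xout = seq_along(v),
                            rule = 2)$y
    as.integer(2L * round(filled) + 1L)
  }))
  # larger sites need larger integer steps to traverse their posterior
  jumps <- as.integer(pmax(control$latent_jump,
                           ceiling(apply(N_init, 1, max) / 20)))

  n_keep <- length(seq(control$n_burnin, control$n_iter - 1L,
                       by = control$thin))
  draws <- array(NA_real_, c(n_keep, 18, control$n_chains),
                 dimnames = list(NULL, nm, paste0("chain", seq_len(control$n_chains))))
  N_draws <- array(NA_real_, c(n_keep, nrow(X) * ncol(X), control$n_chains))
  S_draws <- R_draws <- array(NA_integer_, dim(N_draws))
  accept <- vector("list", control$n_chains)
  for (ch in seq_len(control$n_chains)) {
    set.seed(seed + ch - 1L)
    th <- theta0
    jit <- stats::rnorm(18, 0, 0.3) * update_mask
    th <- th + jit
    th["p_effort"] <- max(th["p_effort"], 0.05)
    th["p_temp"] <- min(th["p_temp"], -0.05)
    res <- dmm_mcmc_chain(X, as.vector(d$Z), d$effort_z, sdE, d$temp_z,
                          as.numeric(th), update_mask, N_init,
                          control$prior_sd, control$n_iter,
                          control$n_burnin, control$thin, jumps,
                          control$latent_sweeps, control$joint_reps)
    draws[, , ch] <- res$theta[seq_len(n_keep), , drop = FALSE]
    N_draws[, , ch] <- res$N[seq_len(n_keep), , drop = FALSE]
    S_draws[, , ch] <- res$S[seq_len(n_keep), , drop = FALSE]
    R_draws[, , ch] <- res$R[seq_len(n_keep), , drop = FALSE]
    accept[[ch]] <- list(moves = res$accept, coef = res$accept_coef)
  }
  structure(list(draws = draws, N_draws = N_draws, S_draws = S_draws,
                 R_draws = R_draws, accept = accept,
                 circles = panel$circles, years = panel$years,
                 surveyed = d$surveyed, update_mask = update_mask,
                 effort_scaling = c(center = d$effort_center,
                                    scale = d$effort_scale),
                 control = control, seed = seed),
            class = "dmm_fit")
}

#' @export
print.dmm_fit <- function(x, ...) {
  cat("Open-population model fit:", dim(x$draws)[3], "chains x",
      dim(x$draws)[1], "kept draws (", x$control$preset, "preset )\n")
  mon <- x$update_mask
  if (dim(x$draws)[3] >= 2) {
    rh <- gelman_rubin(x)
    cat("  max Gelman-Rubin over monitored coefficients:",
        sprintf("%.3f", max(rh[mon])), "\n")
  }
  invisible(x)
}

#' Gelman-Rubin potential scale reduction
#'
#' Between/within-chain variance ratio per monitored parameter:
#' `R = sqrt((W + B/n) / W)` with `W` the mean within-chain variance and
#' `B/n` the variance of chain means. Identical chains give exactly 1;
#' values below 1.1 are conventionally read as adequate convergence. This
#' is the plain ratio form, slightly conservative (never below 1) relative
#' to versions carrying a finite-sample deflation term.
#'
#' @param x a `dmm_fit` or a draws array (iterations x parameters x chains).
#' @return Named numeric vector of statistics, one per parameter.
#' @export
gelman_rubin <- function(x) {
  a <- if (inherits(x, "dmm_fit")) x$draws else x
  if (length(dim(a)) != 3)
    stop("need an iterations x parameters x chains array", call. = FALSE)
  m <- dim(a)[3]; n <- dim(a)[1]
  if (m < 2)
    stop("Gelman-Rubin needs >= 2 chains; rerun with n_chains >= 2",
         call. = FALSE)
  if (n < 10)
    stop("need >= 10 post-burn-in draws per chain", call. = FALSE)
  out <- apply(a, 2, function(d) {
    W <- mean(apply(d, 2, stats::var))
    B_over_n <- stats::var(colMeans(d))
    if (W == 0) return(if (B_over_n == 0) 1 else Inf)
    sqrt((W + B_over_n) / W)
  })
  names(out) <- dimnames(a)[[2]]
  out
}

#' Posterior abundance summaries
#'
#' Posterior mean, central 95% credible interval and effective sample size
#' of the latent abundance `N[i,t]` per circle-year, pooled across chains,
#' plus the region-wide per-year mean across circles (the quantity the
#' trend analysis consumes).
#'
#' @param fit a `dmm_fit` from [sample_posterior()].
#' @return A list with `cells` (data.frame: circle, year, mean, lo95, hi95,
#'   ess) and `yearly` (data.frame: year, mean_abundance).
#' @export
summarize_abundance <- function(fit) {
  stopifnot(inherits(fit, "dmm_fit"))
  I <- length(fit$circles); T <- length(fit$years)
  nd <- fit$N_draws
  pooled <- matrix(aperm(nd, c(1, 3, 2)), nrow = dim(nd)[1] * dim(nd)[3])
  mu <- colMeans(pooled)
  qs <- apply(pooled, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  ess <- apply(nd, 2, function(d) sum(apply(d, 2, ess_one)))
  cells <- data.frame(circle = rep(fit$circles, times = T),
                      year = rep(fit$years, each = I),
                      mean = mu, lo95 = qs[1, ], hi95 = qs[2, ], ess = ess,
                      stringsAsFactors = FALSE)
  mu_mat <- matrix(mu, I, T)
  yearly <- data.frame(year = fit$years, mean_abundance = colMeans(mu_mat))
  list(cells = cells, yearly = yearly)
}

# effective sample size of one chain via initial positive autocorrelations
ess_one <- function(x) {
  n <- length(x)
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(n)
  rho <- stats::acf(x, lag.max = min(100, n - 1), plot = FALSE,
                    demean = TRUE)$acf[-1]
  pos <- which(rho < 0.05)
  if (length(pos)) rho <- rho[seq_len(pos[1] - 1)]
  n / (1 + 2 * sum(rho))
}
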