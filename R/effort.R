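#' Fit a gamma-shaped effort curve to one circle's party hours
#'
#' Nonlinear least squares of
#' `hours ~ amplitude * g(year - onset_year; shape, scale)`, where `g` is
#' the gamma probability density -- the characteristic slow-start /
#' mid-century-growth shape of count effort. Fitting is multimodal, so the
#' optimizer is restarted from the default initialization (onset at the
#' circle's first sampled year) plus perturbed starts; the lowest-SSE
#' converged fit wins. Positivity of amplitude, shape and scale is enforced
#' by optimizing on the log scale.
#'
#' @param years calendar years with recorded effort.
#' @param hours recorded party hours (> 0), same length.
#' @param n_starts number of perturbed restarts beyond the default start.
#' @return A list of class `gamma_curve_fit` with `amplitude`, `shape`,
#'   `scale`, `onset_year`, `residual_se`, `n_points` and `converged`.
#'   Non-convergence from every start returns `converged = FALSE` (callers
#'   fall back to the smoother) rather than an error.
#' @export
fit_effort_curve <- function(years, hours, n_starts = 3) {
  if (length(years) != length(hours))
    stop("years and hours must have equal length", call. = FALSE)
  ok <- !is.na(hours)
  years <- years[ok]; hours <- hours[ok]
  if (length(years) < 5)
    stop("at least 5 observed (year, hours) pairs are required to fit the ",
         "effort curve; got ", length(years), call. = FALSE)
  if (any(hours <= 0)) stop("party hours must be positive", call. = FALSE)

  curve_fun <- function(yr, la, lk, ls, onset)
    exp(la) * stats::dgamma(yr - onset, shape = exp(lk), scale = exp(ls))

  peak_year <- years[which.max(hours)]
  base_start <- list(la = log(max(hours) * 40), lk = log(3),
                     ls = log(max((peak_year - min(years)) / 2, 5)),
                     onset = min(years))
  # fixed perturbation ladder: deterministic, leaves the caller's RNG alone
  perturb <- list(c(0.5, 0.3, -0.3, -10), c(-0.5, -0.3, 0.3, -20),
                  c(0.0, 0.5, 0.5, -5), c(0.3, -0.5, 0.2, -15),
                  c(-0.3, 0.2, -0.5, -25))
  starts <- list(base_start)
  for (s in seq_len(min(n_starts, length(perturb)))) {
    d <- perturb[[s]]
    starts[[s + 1]] <- list(la = base_start$la + d[1],
                            lk = base_start$lk + d[2],
                            ls = base_start$ls + d[3],
                            onset = base_start$onset + d[4])
  }
  best <- NULL; best_sse <- Inf
  for (st in starts) {
    # restarts probe regions where the curve degenerates (onset past the
    # first year); the optimizer recovers, so numeric warnings are noise
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nlsLM(hours ~ curve_fun(years, la, lk, ls, onset),
                          start = st,
                          control = minpack.lm::nls.lm.control(maxiter = 500))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (sse < best_sse) { best <- fit; best_sse <- sse }
  }
  if (is.null(best)) {
    return(structure(list(amplitude = NA_real_, shape = NA_real_,
                          scale = NA_real_, onset_year = NA_real_,
                          residual_se = NA_real_, n_points = length(years),
                          converged = FALSE),
                     class = "gamma_curve_fit"))
  }
  cf <- stats::coef(best)
  structure(list(amplitude = exp(cf[["la"]]), shape = exp(cf[["lk"]]),
                 scale = exp(cf[["ls"]]), onset_year = cf[["onset"]],
                 residual_se = sqrt(best_sse / max(length(years) - 4, 1)),
                 n_points = length(years), converged = TRUE),
            class = "gamma_curve_fit")
}

#' @export
print.gamma_curve_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Gamma effort curve: fit did not converge (", x$n_points,
        "points )\n")
  } else {
    cat(sprintf(
      "Gamma effort curve: amplitude %.1f, shape %.2f, scale %.1f y, onset %.1f (se %.2f, n %d)\n",
      x$amplitude, x$shape, x$scale, x$onset_year, x$residual_se, x$n_points))
  }
  invisible(x)
}

#' Predict effort from a fitted gamma curve
#'
#' Point predictions from the fitted curve with 2-standard-error prediction
#' intervals; `width = upper - lower = 4 * residual_se`. Predictions below
#' the positivity floor are clipped (a detection model needs strictly
#' positive effort) and flagged in the `clipped` column.
#'
#' @param fit a converged [fit_effort_curve()] result.
#' @param years years at which to predict.
#' @param floor minimum admissible party hours.
#' @return data.frame with `year`, `fit`, `lower`, `upper`, `width`,
#'   `clipped`.
#' @export
predict_effort <- function(fit, years, floor = 0.1) {
  stopifnot(inherits(fit, "gamma_curve_fit"))
  if (!fit$converged)
    stop("cannot predict from a non-converged gamma curve fit", call. = FALSE)
  pred <- fit$amplitude * stats::dgamma(years - fit$onset_year,
                                        shape = fit$shape, scale = fit$scale)
  clipped <- pred < floor
  pred <- pmax(pred, floor)
  data.frame(year = years, fit = pred,
             lower = pred - 2 * fit$residual_se,
             upper = pred + 2 * fit$residual_se,
             width = 4 * fit$residual_se, clipped = clipped)
}

#' Local-regression smoothing of recorded effort
#'
#' Loess smoothing of party hours against year for the modern, almost
#' completely recorded era, with 2-SE prediction intervals at the requested
#' target years. Target years outside the observed span are refused (the
#' local smoother does not extrapolate; those years fall back to the gamma
#' curve) and returned in the `"deferred"` attribute.
#'
#' @param years years with recorded effort (>= 10 required).
#' @param hours recorded party hours.
#' @param target_years years at which predictions are wanted.
#' @param span loess span.
#' @return data.frame with `year`, `fit`, `lower`, `upper`, `width` for the
#'   in-span target years (zero rows when there are none), with attribute
#'   `"deferred"` listing refused years.
#' @export
smooth_effort <- function(years, hours, target_years, span = 0.75) {
  ok <- !is.na(hours)
  years <- years[ok]; hours <- hours[ok]
  if (length(years) < 10)
    stop("at least 10 observed points are required for the effort smoother",
         call. = FALSE)
  inside <- target_years >= min(years) & target_years <= max(years)
  deferred <- target_years[!inside]
  target_years <- target_years[inside]
  if (!length(target_years)) {
    out <- data.frame(year = integer(), fit = numeric(), lower = numeric(),
                      upper = numeric(), width = numeric())
    attr(out, "deferred") <- deferred
    return(out)
  }
  lo <- stats::loess(hours ~ years, span = span, degree = 2,
                     control = stats::loess.control(surface = "direct"))
  pr <- stats::predict(lo, newdata = data.frame(years = target_years),
                       se = TRUE)
  out <- data.frame(year = target_years, fit = as.numeric(pr$fit),
                    lower = as.numeric(pr$fit - 2 * pr$se.fit),
                    upper = as.numeric(pr$fit + 2 * pr$se.fit),
                    width = as.numeric(4 * pr$se.fit))
  attr(out, "deferred") <- deferred
  out
}

#' Assemble a complete effort series for one circle
#'
#' Combines recorded effort with the two imputation routes: years with
#' recorded party hours are kept verbatim (interval width 0); missing years
#' before `cutoff` are filled from the gamma curve; missing years from
#' `cutoff` on are filled by the loess smoother where it applies, falling
#' back to the gamma curve outside the smoother's span (and vice versa when
#' one route is unavailable). Every year in `years` is covered or an error
#' names the uncoverable year.
#'
#' @param years all calendar years the series must cover.
#' @param observed numeric vector along `years`; recorded party hours, `NA`
#'   where unrecorded.
#' @param gamma_fit optional pre-computed [fit_effort_curve()]; fitted from
#'   `observed` when `NULL`.
#' @param cutoff first year of the consistently recorded era (1967).
#' @param span loess span for the modern-era smoother.
#' @param floor positivity floor for imputed effort.
#' @param circle circle label used in error messages.
#' @return data.frame of class `effort_series`: `year`, `effort`, `width`
#'   (0 exactly where observed), `source` in
#'   `{"observed", "gamma", "smoother"}`.
#' @export
assemble_effort <- function(years, observed, gamma_fit = NULL, cutoff = 1967,
                            span = 0.75, floor = 0.1, circle = "?") {
  stopifnot(length(years) == length(observed))
  out <- data.frame(year = years, effort = observed,
                    width = ifelse(is.na(observed), NA_real_, 0),
                    source = ifelse(is.na(observed), NA_character_,
                                    "observed"),
                    stringsAsFactors = FALSE)
  miss <- which(is.na(observed))
  if (!length(miss)) {
    class(out) <- c("effort_series", class(out))
    return(out)
  }
  obs_years <- years[!is.na(observed)]
  obs_hours <- observed[!is.na(observed)]
  if (is.null(gamma_fit))
    gamma_fit <- tryCatch(fit_effort_curve(obs_years, obs_hours),
                          error = function(e) NULL)
  gamma_ok <- !is.null(gamma_fit) && isTRUE(gamma_fit$converged)

  post <- obs_years >= cutoff
  smoother <- NULL
  if (sum(post) >= 10) {
    targets <- years[miss][years[miss] >= cutoff]
    if (length(targets))
      smoother <- tryCatch(
        smooth_effort(obs_years[post], obs_hours[post], targets, span = span),
        error = function(e) NULL)
  }
  for (j in miss) {
    yr <- years[j]
    filled <- FALSE
    if (yr >= cutoff && !is.null(smoother) && yr %in% smoother$year) {
      row <- smoother[smoother$year == yr, ]
      out$effort[j] <- max(row$fit, floor)
      out$width[j] <- row$width
      out$source[j] <- "smoother"
      filled <- TRUE
    } else if (gamma_ok) {
      pr <- predict_effort(gamma_fit, yr, floor = floor)
      out$effort[j] <- pr$fit
      out$width[j] <- pr$width
      out$source[j] <- "gamma"
      filled <- TRUE
    } else if (!is.null(smoother) && yr %in% smoother$year) {
      row <- smoother[smoother$year == yr, ]
      out$effort[j] <- max(row$fit, floor)
      out$width[j] <- row$width
      out$source[j] <- "smoother"
      filled <- TRUE
    }
    if (!filled)
      stop("cannot impute effort for circle ", circle, ", year ", yr,
           ": gamma curve and smoother both unavailable", call. = FALSE)
  }
  class(out) <- c("effort_series", class(out))
  out
}

#' Impute missing effort across a whole panel
#'
#' Runs [assemble_effort()] independently for every circle (each circle has
#' its own effort history) and writes the imputed party hours and interval
#' widths back into the panel. Observed entries are never altered.
#'
#' @param panel an [obs_panel()].
#' @param cutoff,span,floor passed to [assemble_effort()].
#' @return The panel with complete `effort` and `effort_width` matrices and
#'   an `"effort_source"` attribute (character matrix).
#' @export
impute_effort <- function(panel, cutoff = 1967, span = 0.75, floor = 0.1) {
  stopifnot(inherits(panel, "obs_panel"))
  src <- matrix(NA_character_, length(panel$circles), length(panel$years))
  for (i in seq_along(panel$circles)) {
    es <- assemble_effort(panel$years, panel$effort[i, ], cutoff = cutoff,
                          span = span, floor = floor,
                          circle = panel$circles[i])
    panel$effort[i, ] <- es$effort
    panel$effort_width[i, ] <- es$width
    src[i, ] <- es$source
  }
  attr(panel, "effort_source") <- src
  panel
}
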