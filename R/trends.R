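#' Region-wide mean abundance series, trimmed to the detection window
#'
#' Per-year arithmetic mean of circle-level posterior mean abundances,
#' restricted to the span between the first and last year the species was
#' actually detected -- population size is never extrapolated beyond the
#' window the data support.
#'
#' @param estimates data.frame with columns `circle`, `year`, `mean` (the
#'   `cells` element of [summarize_abundance()] works directly).
#' @param detections data.frame with columns `circle`, `year` and logical
#'   `detected` (or a count column `count`, where detection means
#'   `count > 0`).
#' @return data.frame with `year` and `abundance`, one row per retained
#'   year, with attribute `"trim_range"`.
#' @export
mean_abundance_series <- function(estimates, detections) {
  stopifnot(all(c("circle", "year", "mean") %in% names(estimates)))
  if (!"detected" %in% names(detections)) {
    if (!"count" %in% names(detections))
      stop("detections needs a `detected` or `count` column", call. = FALSE)
    detections$detected <- !is.na(detections$count) & detections$count > 0
  }
  det_years <- detections$year[detections$detected]
  if (!length(det_years))
    stop("species was never detected; no trend series can be formed",
         call. = FALSE)
  lo <- min(det_years); hi <- max(det_years)
  keep <- estimates$year >= lo & estimates$year <= hi
  agg <- stats::aggregate(mean ~ year, data = estimates[keep, ], FUN = mean)
  out <- data.frame(year = agg$year, abundance = agg$mean)
  out <- out[order(out$year), ]
  rownames(out) <- NULL
  attr(out, "trim_range") <- c(first_detection = lo, last_detection = hi)
  out
}

#' Smooth an abundance series with a penalized-spline GAM
#'
#' Fits `abundance ~ s(year)` with a cubic regression spline; if that basis
#' errors, a thin-plate regression spline is tried instead and the basis
#' actually used is recorded. The smoothing dimension defaults to
#' `min(10, floor(n/4))` (never below 4 -- too few knots degenerate the
#' basis). The fitted values and the 3-year first-derivative series are
#' returned together.
#'
#' @param series data.frame with `year` and `abundance` (consecutive years).
#' @param k basis dimension; `NULL` for the default above.
#' @return An object of class `trend_curve`: `years`, `fitted`,
#'   `derivative` (see [derivative_series()]), `basis`
#'   (`"cubic-spline"` or `"thin-plate"`), `trim_range`.
#' @export
fit_trend <- function(series, k = NULL) {
  stopifnot(all(c("year", "abundance") %in% names(series)))
  series <- series[order(series$year), ]
  n <- nrow(series)
  if (n < 8)
    stop("trend fitting needs at least 8 yearly values; got ", n,
         call. = FALSE)
  if (is.null(k)) k <- max(4, min(10, floor(n / 4)))
  dat <- data.frame(year = series$year, abundance = series$abundance)
  fit <- tryCatch(
    mgcv::gam(abundance ~ s(year, bs = "cr", k = k), data = dat),
    error = function(e) NULL)
  basis <- "cubic-spline"
  if (is.null(fit)) {
    fit <- tryCatch(
      mgcv::gam(abundance ~ s(year, bs = "tp", k = k), data = dat),
      error = function(e) NULL)
    basis <- "thin-plate"
  }
  if (is.null(fit))
    stop("GAM fitting failed with both cubic and thin-plate bases for this ",
         "series", call. = FALSE)
  fitted <- as.numeric(stats::fitted(fit))
  tr <- attr(series, "trim_range")
  if (is.null(tr)) tr <- c(first_detection = min(series$year),
                           last_detection = max(series$year))
  curve <- structure(list(years = series$year, fitted = fitted,
                          basis = basis, trim_range = tr, k = k),
                     class = "trend_curve")
  curve$derivative <- derivative_series(curve)
  curve
}

#' @export
print.trend_curve <- function(x, ...) {
  cat("Trend curve over", length(x$years), "years (", min(x$years), "-",
      max(x$years), "), basis:", x$basis, "\n")
  cat("  ", length(x$derivative$value), "three-year derivative steps\n")
  invisible(x)
}

#' First derivatives of a fitted trend over 3-year intervals
#'
#' Finite differences of the fitted trend over consecutive non-overlapping
#' 3-year windows anchored at the series start: step `j` is
#' `fitted(y0 + 3j) - fitted(y0 + 3(j-1))`. Positive values mean increasing
#' abundance. A series shorter than one full step returns an empty
#' derivative with a warning.
#'
#' @param curve a `trend_curve` (or any list with `years` and `fitted`).
#' @param step interval length in years.
#' @return data.frame with `year` (start of each window) and `value`.
#' @export
derivative_series <- function(curve, step = 3) {
  years <- curve$years; fitted <- curve$fitted
  n <- length(years)
  n_steps <- (n - 1) %/% step
  if (n_steps < 1) {
    warning("series spans less than one ", step, "-year interval; empty ",
            "derivative", call. = FALSE)
    return(data.frame(year = integer(), value = numeric()))
  }
  idx0 <- 1 + (seq_len(n_steps) - 1) * step
  data.frame(year = years[idx0],
             value = fitted[idx0 + step] - fitted[idx0])
}

#' Classify derivative runs and non-stationarity
#'
#' Finds the maximal same-sign runs of the 3-year derivative series
#' (derivatives exactly zero, within `tol`, break runs and count toward
#' neither direction) and derives the study's non-stationarity flags:
#' a trajectory is non-stationary when it contains both an increasing and a
#' decreasing run of at least `dual` years; `decline15` flags a decreasing
#' run of at least `decline` years and `increase8` an increasing run of at
#' least `increase` years. Run lengths are measured in years
#' (`years_per_step` per derivative step).
#'
#' @param derivatives numeric vector of derivative values, or the
#'   data.frame from [derivative_series()].
#' @param thresholds named numeric vector `c(dual=, decline=, increase=)`
#'   in years.
#' @param years_per_step years spanned by one derivative step.
#' @param tol absolute tolerance below which a derivative counts as zero.
#' @return A list of class `run_classification`: `runs` (data.frame
#'   `direction`, `start_step`, `length_steps`, `length_years`),
#'   `nonstationary`, `decline15`, `increase8`.
#' @export
classify_runs <- function(derivatives,
                          thresholds = c(dual = 5, decline = 15, increase = 8),
                          years_per_step = 3, tol = 1e-12) {
  v <- if (is.data.frame(derivatives)) derivatives$value else derivatives
  if (!length(v))
    stop("derivative series is empty; nothing to classify", call. = FALSE)
  sgn <- ifelse(abs(v) <= tol, 0L, ifelse(v > 0, 1L, -1L))
  r <- rle(sgn)
  ends <- cumsum(r$lengths)
  runs <- data.frame(
    direction = c("decreasing", "zero", "increasing")[r$values + 2],
    start_step = ends - r$lengths + 1L,
    length_steps = r$lengths)
  runs$length_years <- runs$length_steps * years_per_step
  inc <- runs$length_years[runs$direction == "increasing"]
  dec <- runs$length_years[runs$direction == "decreasing"]
  structure(list(
    runs = runs,
    nonstationary = any(inc >= thresholds[["dual"]]) &&
      any(dec >= thresholds[["dual"]]),
    decline15 = any(dec >= thresholds[["decline"]]),
    increase8 = any(inc >= thresholds[["increase"]])),
    class = "run_classification")
}

#' @export
print.run_classification <- function(x, ...) {
  cat("Run classification:", nrow(x$runs), "maximal runs\n")
  cat("  nonstationary:", x$nonstationary, " decline15:", x$decline15,
      " increase8:", x$increase8, "\n")
  invisible(x)
}

#' Resample a trend curve onto a fixed-length common grid
#'
#' Linear time-rescaling of a fitted trend to `n_points` equally spaced
#' points over its own span, so trends observed over different year ranges
#' become comparable rows of one clustering matrix.
#'
#' @param years,fitted the curve to resample.
#' @param n_points grid length.
#' @return Numeric vector of length `n_points`.
#' @export
trend_to_grid <- function(years, fitted, n_points = 100) {
  if (length(years) < 2) stop("need at least 2 points", call. = FALSE)
  stats::approx(x = seq(0, 1, length.out = length(years)), y = fitted,
                xout = seq(0, 1, length.out = n_points))$y
}
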