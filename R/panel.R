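#' Observation panel for one species
#'
#' Container for a circle-by-year panel of winter count data for a single
#' species: observed counts, sampling effort (total party hours, with `NA`
#' where effort was not recorded), effort prediction-interval widths,
#' per-survey minimum temperature, and site covariates.
#'
#' Counts are `NA` at circle-years where no survey took place; effort can be
#' `NA` at surveyed circle-years where party hours were not recorded (common
#' before 1967), which is exactly the situation the effort-imputation and
#' measurement-error machinery addresses.
#'
#' @param counts integer matrix, circles x years; `NA` = not surveyed.
#' @param effort numeric matrix, same shape; party hours, `NA` = unrecorded.
#' @param temp numeric matrix, same shape; minimum temperature (deg C).
#' @param covariates list with elements `elevation` (length-I vector, m),
#'   `habitat` (I x T matrix, km^2 of preferred habitat), `developed`
#'   (I x T, km^2 developed land), `density` (I x T, persons/km^2).
#' @param years integer vector of calendar years (columns).
#' @param circles character vector of circle identifiers (rows).
#' @param effort_width optional numeric matrix of effort prediction-interval
#'   widths (0 where effort was observed); filled in by [impute_effort()].
#'
#' @return An object of class `obs_panel`.
#' @export
obs_panel <- function(counts, effort, temp, covariates, years,
                      circles = rownames(counts), effort_width = NULL) {
  counts <- as.matrix(counts)
  I <- nrow(counts); T <- ncol(counts)
  if (is.null(circles)) circles <- paste0("circle_", seq_len(I))
  stopifnot(length(years) == T, length(circles) == I)
  for (m in list(effort, temp)) {
    if (!all(dim(as.matrix(m)) == c(I, T)))
      stop("counts, effort and temp must share dimensions", call. = FALSE)
  }
  need <- c("elevation", "habitat", "developed", "density")
  if (!all(need %in% names(covariates)))
    stop("covariates must contain: ", paste(need, collapse = ", "), call. = FALSE)
  if (length(covariates$elevation) != I)
    stop("elevation must have one value per circle", call. = FALSE)
  for (nm in c("habitat", "developed", "density")) {
    if (!all(dim(as.matrix(covariates[[nm]])) == c(I, T)))
      stop(nm, " covariate must be an I x T matrix", call. = FALSE)
  }
  if (is.null(effort_width)) {
    effort_width <- matrix(0, I, T)
    effort_width[is.na(effort)] <- NA_real_
  }
  x <- list(counts = counts, effort = as.matrix(effort),
            effort_width = as.matrix(effort_width), temp = as.matrix(temp),
            covariates = covariates, years = as.integer(years),
            circles = as.character(circles))
  class(x) <- "obs_panel"
  x
}

#' @export
print.obs_panel <- function(x, ...) {
  surveyed <- sum(!is.na(x$counts))
  cat("Observation panel:", length(x$circles), "circles x",
      length(x$years), "years (", min(x$years), "-", max(x$years), ")\n")
  cat("  surveyed circle-years:", surveyed,
      sprintf("(%.1f%%)", 100 * surveyed / length(x$counts)), "\n")
  cat("  effort recorded at:", sum(!is.na(x$effort)), "circle-years\n")
  invisible(x)
}

#' Apply the study's data-inclusion filters
#'
#' Removes circles sampled fewer than `min_circle_samplings` times over the
#' panel's span, and circles where the species was detected (count > 0) fewer
#' than `min_species_detections` times. Both thresholds are strict
#' "fewer than" rules, so a circle sampled exactly 30 times is retained.
#'
#' @param panel an [obs_panel()].
#' @param min_circle_samplings minimum number of surveyed years per circle.
#' @param min_species_detections minimum number of years with a positive count.
#' @return The filtered `obs_panel`, with an attribute `"removed"` -- a
#'   data.frame of removed circles and the reason -- and attribute
#'   `"n_removed"`. If no circle survives, the (empty) panel is returned with
#'   a warning rather than an error.
#' @export
apply_study_filters <- function(panel, min_circle_samplings = 30,
                                min_species_detections = 10) {
  stopifnot(inherits(panel, "obs_panel"))
  sampled <- rowSums(!is.na(panel$counts))
  detected <- rowSums(panel$counts > 0, na.rm = TRUE)
  drop_sampling <- sampled < min_circle_samplings
  drop_detection <- !drop_sampling & detected < min_species_detections
  keep <- !(drop_sampling | drop_detection)
  removed <- data.frame(
    circle = panel$circles[!keep],
    reason = ifelse(drop_sampling[!keep], "insufficient_samplings",
                    "insufficient_detections"),
    n_sampled = sampled[!keep], n_detected = detected[!keep],
    stringsAsFactors = FALSE)
  if (!any(keep))
    warning("no circles pass the study filters; returning empty panel",
            call. = FALSE)
  out <- subset_panel(panel, which(keep))
  attr(out, "removed") <- removed
  attr(out, "n_removed") <- nrow(removed)
  out
}

# Row-subset a panel (internal).
subset_panel <- function(panel, idx) {
  cov <- panel$covariates
  cov$elevation <- cov$elevation[idx]
  for (nm in c("habitat", "developed", "density"))
    cov[[nm]] <- cov[[nm]][idx, , drop = FALSE]
  extra <- setdiff(names(panel$covariates), c("elevation", "habitat",
                                              "developed", "density"))
  for (nm in extra) {
    v <- panel$covariates[[nm]]
    cov[[nm]] <- if (is.matrix(v)) v[idx, , drop = FALSE] else v[idx]
  }
  obs_panel(panel$counts[idx, , drop = FALSE],
            panel$effort[idx, , drop = FALSE],
            panel$temp[idx, , drop = FALSE],
            cov, panel$years, panel$circles[idx],
            panel$effort_width[idx, , drop = FALSE])
}

#' Convert a panel to a tidy data.frame
#'
#' One row per circle-year with counts, effort, effort interval width,
#' temperature and covariates; the format written to and read from disk.
#'
#' @param x an [obs_panel()].
#' @param ... unused.
#' @return A data.frame with one row per circle-year.
#' @export
as.data.frame.obs_panel <- function(x, ...) {
  I <- length(x$circles); T <- length(x$years)
  data.frame(
    circle = rep(x$circles, times = T),
    year = rep(x$years, each = I),
    count = as.vector(x$counts),
    effort_hours = as.vector(x$effort),
    effort_width = as.vector(x$effort_width),
    min_temp = as.vector(x$temp),
    elevation = rep(x$covariates$elevation, times = T),
    habitat_area = as.vector(x$covariates$habitat),
    developed_area = as.vector(x$covariates$developed),
    human_density = as.vector(x$covariates$density),
    stringsAsFactors = FALSE)
}
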