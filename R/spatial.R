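#' Cluster-type composition of one circle
#'
#' Tally of trend-cluster labels over the species present at a circle,
#' optionally restricted to one habitat guild, with proportions.
#'
#' @param assignments data.frame with columns `circle`, `species`, `label`
#'   (1..k) and optionally `guild`.
#' @param circle circle identifier.
#' @param guild_filter optional guild name; only species of that guild are
#'   counted.
#' @param k number of cluster types.
#' @return A list with `circle`, `guild`, `counts` (length k), `proportions`
#'   (sum to 1 when any species counted), `total`, and `empty` (TRUE when no
#'   species survive the filter).
#' @export
circle_composition <- function(assignments, circle, guild_filter = NULL,
                               k = 4) {
  stopifnot(all(c("circle", "species", "label") %in% names(assignments)))
  rows <- assignments[assignments$circle == circle, ]
  if (!is.null(guild_filter)) {
    if (!"guild" %in% names(rows))
      stop("assignments has no `guild` column", call. = FALSE)
    rows <- rows[rows$guild == guild_filter, ]
  }
  counts <- tabulate(rows$label, nbins = k)
  total <- sum(counts)
  list(circle = circle, guild = guild_filter, counts = counts,
       proportions = if (total > 0) counts / total else rep(NA_real_, k),
       total = total, empty = total == 0)
}

#' Chi-square dominance test of cluster composition
#'
#' Goodness-of-fit of the observed cluster-type counts against the expected
#' composition (uniform 1/k by default), `df = k - 1`. A dominant cluster
#' label is reported only when the test is significant at `alpha`; ties in
#' the maximal count break toward the lowest label. Circles with fewer than
#' `min_total` species are left untested (the chi-square approximation is
#' unreliable there) and return `tested = FALSE`.
#'
#' @param counts nonnegative integer vector of per-cluster counts.
#' @param alpha significance level.
#' @param expected expected proportions under the null; uniform by default.
#' @param min_total minimum total count for testing.
#' @return A list with `statistic`, `p_value`, `dominant_label` (`NA`
#'   unless significant), `tested`.
#' @export
dominance_test <- function(counts, alpha = 0.05, expected = NULL,
                           min_total = 8) {
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  kk <- length(counts)
  if (is.null(expected)) expected <- rep(1 / kk, kk)
  stopifnot(length(expected) == kk, abs(sum(expected) - 1) < 1e-8)
  total <- sum(counts)
  if (total < min_total)
    return(list(statistic = NA_real_, p_value = NA_real_,
                dominant_label = NA_integer_, tested = FALSE))
  E <- total * expected
  stat <- sum((counts - E)^2 / E)
  p <- stats::pchisq(stat, df = kk - 1, lower.tail = FALSE)
  dom <- if (p < alpha) which.max(counts) else NA_integer_
  list(statistic = stat, p_value = p, dominant_label = dom, tested = TRUE)
}

#' Summarize cluster composition for every circle
#'
#' Runs [circle_composition()] and [dominance_test()] for each circle
#' (optionally within one guild) and returns one row per circle -- the table
#' behind dominant-medoid maps. No multiple-testing correction is applied
#' across circles (the test is used descriptively); this is recorded in the
#' returned attributes.
#'
#' @param assignments data.frame with `circle`, `species`, `label`, and
#'   optionally `guild`.
#' @param guild_filter optional guild restriction.
#' @param k number of cluster types.
#' @param alpha,expected,min_total passed to [dominance_test()].
#' @return data.frame with circle, per-cluster counts (`n1..nk`),
#'   proportions, `total`, `statistic`, `p_value`, `dominant_label`,
#'   `tested`.
#' @export
summarize_circles <- function(assignments, guild_filter = NULL, k = 4,
                              alpha = 0.05, expected = NULL, min_total = 8) {
  circles <- unique(assignments$circle)
  rows <- lapply(circles, function(cc) {
    comp <- circle_composition(assignments, cc, guild_filter, k)
    tst <- dominance_test(comp$counts, alpha, expected, min_total)
    out <- data.frame(circle = cc, total = comp$total,
                      statistic = tst$statistic, p_value = tst$p_value,
                      dominant_label = tst$dominant_label,
                      tested = tst$tested, stringsAsFactors = FALSE)
    for (j in seq_len(k)) out[[paste0("n", j)]] <- comp$counts[j]
    for (j in seq_len(k)) out[[paste0("prop", j)]] <- comp$proportions[j]
    out
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "multiple_testing_correction") <- "none"
  attr(out, "expected") <- if (is.null(expected)) rep(1 / k, k) else expected
  out
}

#' Per-circle cluster labels for one species
#'
#' Extracts the circle-level medoid association of a single species -- the
#' table from which a species' trend-type map is drawn.
#'
#' @param assignments data.frame with `circle`, `species`, `label`.
#' @param species species identifier.
#' @return data.frame with `circle` and `label`, one row per circle where
#'   the species has an assignment.
#' @export
species_circle_map <- function(assignments, species) {
  stopifnot(all(c("circle", "species", "label") %in% names(assignments)))
  rows <- assignments[assignments$species == species, c("circle", "label")]
  if (!nrow(rows))
    stop("no assignments found for species '", species, "'", call. = FALSE)
  rownames(rows) <- NULL
  rows
}
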