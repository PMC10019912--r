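#' Standardize trend curves for clustering
#'
#' Transforms each row (one trend on a common time grid) to mean 0, sd 1,
#' so that clustering compares shapes rather than abundance scales; any two
#' affine transforms of the same shape map to the identical standardized
#' row. Constant rows carry no shape and are excluded, with their indices
#' recorded in the `"excluded"` attribute.
#'
#' @param m numeric matrix, one trend per row.
#' @return Standardized matrix (possibly fewer rows), with attributes
#'   `"excluded"` (original row indices dropped) and `"kept"`.
#' @export
standardize_trends <- function(m) {
  m <- as.matrix(m)
  sds <- apply(m, 1, stats::sd)
  excluded <- which(sds == 0 | !is.finite(sds))
  if (length(excluded))
    message(length(excluded), " constant trend row(s) excluded from ",
            "standardization: ", paste(utils::head(excluded, 10), collapse = ", "))
  excluded <- unname(excluded)
  kept <- setdiff(seq_len(nrow(m)), excluded)
  out <- (m[kept, , drop = FALSE] - rowMeans(m[kept, , drop = FALSE])) /
    sds[kept]
  attr(out, "excluded") <- excluded
  attr(out, "kept") <- kept
  out
}

#' Partitioning around medoids of trend curves
#'
#' k-medoids with Euclidean dissimilarity on standardized trend rows.
#' Small instances (at most `exact_limit` candidate medoid subsets) are
#' solved exactly by enumerating every k-subset of rows -- BUILD + SWAP is
#' a heuristic and can land in a local optimum even on a handful of rows,
#' and exact minimisation costs next to nothing there. Larger instances
#' use the classical BUILD + SWAP algorithm, whose total cost is
#' non-increasing over SWAP iterations by construction. Deterministic for
#' a given input.
#'
#' @param m numeric matrix of trends (rows >= k), typically from
#'   [standardize_trends()].
#' @param k number of medoids.
#' @param seed optional seed, accepted for interface symmetry with
#'   [clara_medoids()] (PAM itself is deterministic).
#' @param exact_limit maximum number of medoid subsets enumerated before
#'   switching to BUILD + SWAP.
#' @return An object of class `medoid_result`: `k`, `medoid_indices`,
#'   `medoid_curves`, `assignments` (1..k per row; each medoid assigned to
#'   itself), `total_cost`.
#' @export
pam_medoids <- function(m, k = 4, seed = NULL, exact_limit = 5000) {
  m <- as.matrix(m)
  if (!all(is.finite(m))) {
    bad <- which(apply(m, 1, function(r) any(!is.finite(r))))
    stop("non-finite entries in trend rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  n <- nrow(m)
  if (n < k)
    stop("need at least k = ", k, " rows; got ", n, call. = FALSE)
  if (n == k)  # every row is its own medoid; cost is exactly 0
    return(finalize_medoids(m, seq_len(k), seq_len(k)))
  if (choose(n, k) <= exact_limit) {
    d <- as.matrix(stats::dist(m))
    combos <- utils::combn(n, k)
    costs <- apply(combos, 2, function(idx)
      sum(apply(d[, idx, drop = FALSE], 1, min)))
    best <- combos[, which.min(costs)]
    assignments <- apply(d[, best, drop = FALSE], 1, which.min)
    return(finalize_medoids(m, as.integer(best), as.integer(assignments)))
  }
  if (!is.null(seed)) set.seed(seed)
  res <- cluster::pam(m, k = k, metric = "euclidean", keep.diss = FALSE,
                      keep.data = FALSE)
  finalize_medoids(m, as.integer(res$id.med), as.integer(res$clustering))
}

#' Subsampled PAM for large trend matrices
#'
#' CLARA: PAM is run on random subsamples of the rows; every row of the
#' full matrix is then assigned to its nearest medoid, and the medoid set
#' with the lowest full-data cost wins. Falls back to exact
#' [pam_medoids()] when the matrix has no more rows than one subsample.
#' Reproducible given `seed`.
#'
#' @param m numeric matrix of trends.
#' @param k number of medoids.
#' @param subsample_size rows per subsample (>= k).
#' @param n_subsamples number of subsamples drawn (each without replacement
#'   within itself, independently across subsamples).
#' @param seed integer seed.
#' @return A `medoid_result`, as for [pam_medoids()].
#' @export
clara_medoids <- function(m, k = 4, subsample_size = 1000,
                          n_subsamples = 1000, seed = 1L) {
  m <- as.matrix(m)
  if (subsample_size < k)
    stop("subsample_size must be >= k", call. = FALSE)
  if (nrow(m) <= subsample_size) return(pam_medoids(m, k = k, seed = seed))
  set.seed(seed)
  res <- cluster::clara(m, k = k, metric = "euclidean",
                        samples = n_subsamples,
                        sampsize = subsample_size, pamLike = TRUE,
                        rngR = TRUE, medoids.x = TRUE)
  finalize_medoids(m, as.integer(res$i.med), as.integer(res$clustering))
}

# shared assembly: recompute assignments/cost directly from the medoids so
# both algorithms report the identical cost definition
finalize_medoids <- function(m, medoid_idx, assignments) {
  medoids <- m[medoid_idx, , drop = FALSE]
  d <- distances_to_medoids(m, medoids)
  cost <- sum(d[cbind(seq_len(nrow(m)), assignments)])
  structure(list(k = nrow(medoids), medoid_indices = medoid_idx,
                 medoid_curves = medoids, assignments = assignments,
                 total_cost = cost),
            class = "medoid_result")
}

#' @export
print.medoid_result <- function(x, ...) {
  cat("k-medoids result: k =", x$k, ", n =", length(x$assignments),
      ", total cost", sprintf("%.3f", x$total_cost), "\n")
  cat("  cluster sizes:", tabulate(x$assignments, x$k), "\n")
  invisible(x)
}

#' Assign trends to fixed medoid curves
#'
#' Nearest-medoid labels under Euclidean distance, with ties broken toward
#' the lowest medoid index. Used to propagate a clustering to new or held
#' out trends.
#'
#' @param trends numeric matrix (rows standardized on the medoids' grid).
#' @param medoid_curves k x p matrix of medoid curves.
#' @return Integer vector of labels in 1..k.
#' @export
assign_to_medoids <- function(trends, medoid_curves) {
  trends <- as.matrix(trends)
  medoid_curves <- as.matrix(medoid_curves)
  if (ncol(trends) != ncol(medoid_curves))
    stop("trends have ", ncol(trends), " columns but medoids have ",
         ncol(medoid_curves), call. = FALSE)
  d <- distances_to_medoids(trends, medoid_curves)
  apply(d, 1, which.min)  # which.min takes the first (lowest index) on ties
}

# n x k Euclidean distance matrix; direct differences per medoid, which
# keeps self-distances exactly zero (internal)
distances_to_medoids <- function(m, medoids) {
  k <- nrow(medoids)
  out <- matrix(0, nrow(m), k)
  for (j in seq_len(k))
    out[, j] <- sqrt(rowSums(sweep(m, 2, medoids[j, ])^2))
  out
}
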