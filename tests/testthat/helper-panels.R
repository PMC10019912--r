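# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# A fully-specified panel from raw matrices, with flat covariates unless
# given. Effort defaults to fully recorded (no NA).
make_panel <- function(counts, effort = NULL, temp = NULL, years = NULL,
                       covariates = NULL) {
  counts <- as.matrix(counts)
  I <- nrow(counts); T <- ncol(counts)
  if (is.null(effort)) effort <- matrix(20, I, T)
  if (is.null(temp)) temp <- matrix(seq(-5, 5, length.out = I * T), I, T)
  if (is.null(years)) years <- seq(2001, length.out = T)
  if (is.null(covariates))
    covariates <- list(elevation = seq(100, 900, length.out = I),
                       habitat = matrix(seq(40, 220, length.out = I * T), I, T),
                       developed = matrix(seq(5, 60, length.out = I * T), I, T),
                       density = matrix(seq(10, 80, length.out = I * T), I, T))
  obs_panel(counts, effort, temp, covariates, years = years)
}

# Parameters with zero slopes and the given link-scale intercepts.
flat_params <- function(lam0 = 0, om0 = 0, gam0 = 0,
                        alpha = c(0, 0.5, -0.5)) {
  dmm_params(beta_lambda = c(lam0, 0, 0, 0, 0),
             beta_omega = c(om0, 0, 0, 0, 0),
             beta_gamma = c(gam0, 0, 0, 0, 0),
             alpha = alpha)
}

# Covariate list with constant generators (identical circles) for
# degenerate-input checks.
constant_covariates <- function(I, T) {
  list(elevation = rep(500, I),
       habitat = matrix(100, I, T),
       developed = matrix(20, I, T),
       density = matrix(50, I, T),
       latitude = rep(0.5, I))
}

# Small latent state wrapped in the class the observation generator expects.
make_latent <- function(N, S = NULL, R = NULL) {
  N <- as.matrix(N)
  structure(list(N = N, S = S, R = R), class = "latent_state")
}

# All permutations of 1:k (tiny k only).
perms_of <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in perms_of(k - 1))
    for (pos in seq_len(k))
      out[[length(out) + 1]] <- append(p, k, after = pos - 1)
  out
}

# Best label agreement between a clustering and planted labels over all
# label permutations.
best_label_agreement <- function(assignments, labels, k = 4) {
  max(vapply(perms_of(k),
             function(p) mean(p[assignments] == labels), numeric(1)))
}

# Exhaustive PAM oracle: minimal total cost over all k-subsets of rows.
exhaustive_pam_cost <- function(m, k) {
  n <- nrow(m)
  best <- Inf
  combos <- utils::combn(n, k)
  for (j in seq_len(ncol(combos))) {
    med <- m[combos[, j], , drop = FALSE]
    d <- sapply(seq_len(k), function(l)
      sqrt(rowSums(sweep(m, 2, med[l, ])^2)))
    best <- min(best, sum(apply(as.matrix(d), 1, min)))
  }
  best
}
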