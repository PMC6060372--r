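# Independent oracles and small fixtures shared across tests. These
# re-derive the quantities under test by a different route (dense Riemann
# grids, naive voxel loops, direct dense-matrix algebra) and must stay
# independent of the package's own computation paths.

# Dense Riemann-grid (trapezoid) oracle for the JZS one-sample BF10:
# integrates the Cauchy-mixture representation over u = log g.
riemann_jzs_bf10 <- function(t, n, rscale, n_grid = 200001, lim = 25) {
  u <- seq(-lim, lim, length.out = n_grid)
  g <- exp(u)
  nu <- n - 1
  a <- 1 + n * g * rscale^2
  logf <- -0.5 * log(a) - (nu + 1) / 2 * log1p(t^2 / (a * nu)) -
    0.5 * log(2 * pi) - 0.5 * log(g) - 1 / (2 * g)
  f <- exp(logf)
  alt <- sum((f[-1] + f[-n_grid]) / 2) * (u[2] - u[1])
  null <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  alt / null
}

# Naive voxel-loop re-implementations of the two tract metrics.
naive_seed_ratio <- function(counts, n_samples, min_samples, survivors_only = TRUE) {
  kept <- c()
  for (v in counts) if (v >= min_samples) kept <- c(kept, v)
  if (survivors_only) {
    if (length(kept) == 0) return(0)
    total <- 0
    for (v in kept) total <- total + v / n_samples
    total / length(kept)
  } else {
    total <- 0
    for (v in kept) total <- total + v / n_samples
    total / length(counts)
  }
}

naive_tract_strength <- function(counts, min_samples, n_mask_voxels) {
  n_surv <- 0
  for (v in counts) if (v >= min_samples) n_surv <- n_surv + 1
  n_surv / n_mask_voxels
}

# Direct dense-matrix log marginal likelihood for the mixed model, given g:
# builds Sigma = I + X G X' explicitly (no Woodbury) and integrates the
# location/scale analytically. Same normalisation constant convention as
# the package (constants shared across models cancel in BFs).
dense_log_marginal_given_g <- function(y, X, g_cols) {
  N <- length(y)
  Sigma <- diag(N) + X %*% (g_cols * t(X))
  Si <- solve(Sigma)
  one <- rep(1, N)
  oSo <- drop(t(one) %*% Si %*% one)
  oSy <- drop(t(one) %*% Si %*% y)
  ySy <- drop(t(y) %*% Si %*% y)
  S <- ySy - oSy^2 / oSo
  -0.5 * determinant(Sigma)$modulus[1] - 0.5 * log(oSo) - (N - 1) / 2 * log(S)
}

# 2-D tensor-grid quadrature of the mixed-model marginal over two g
# parameters with inverse-gamma(1/2, r^2/2) priors, on the log-g scale.
dense_grid_marginal_2g <- function(y, X1, r1, X2, r2, n_grid = 80, lim = 12) {
  u <- seq(-lim, lim, length.out = n_grid)
  du <- u[2] - u[1]
  ldig <- function(g, r) 0.5 * log(r^2 / 2) - lgamma(0.5) - 1.5 * log(g) -
    (r^2 / 2) / g
  X <- cbind(X1, X2)
  vals <- matrix(NA_real_, n_grid, n_grid)
  for (i in seq_len(n_grid)) for (j in seq_len(n_grid)) {
    g1 <- exp(u[i]); g2 <- exp(u[j])
    gc <- c(rep(g1, ncol(X1)), rep(g2, ncol(X2)))
    vals[i, j] <- dense_log_marginal_given_g(y, X, gc) +
      ldig(g1, r1) + ldig(g2, r2) + u[i] + u[j]
  }
  m <- max(vals)
  m + log(sum(exp(vals - m)) * du * du)
}

# a compact phantom spec for fast unit tests
small_spec <- function(n_subjects = 3L, n_timepoints = 60L, rng_seed = 11L) {
  ground_truth_spec(n_subjects = n_subjects, n_timepoints = n_timepoints,
                    rng_seed = rng_seed)
}

# a 1000-voxel single-box mask on a small grid
big_test_mask <- function(label = "STN", hemisphere = "L") {
  grid <- volume_grid(c(10, 10, 10))
  roi_mask(grid, 0:999, label, hemisphere)
}
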