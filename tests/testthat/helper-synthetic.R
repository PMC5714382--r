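# Shared fixtures and independent oracles for the test suite.

# small coupled two-region dataset (spec scale: 3 runs x 100 volumes)
quick_spec <- function(rng_seed = 1, ...) {
  args <- list(
    n_runs = 3, timepoints_per_run = 100,
    regions = list(predictor = list(n_voxels = 50, n_latent = 3),
                   seed = list(n_voxels = 50, n_latent = 3)),
    noise_sd = 1, rng_seed = rng_seed)
  args[names(list(...))] <- list(...)
  do.call(synthetic_spec, args)
}

# independent pPCA log-likelihood: evaluates the Gaussian likelihood of the
# model covariance C = W W' + sigma2 I directly against the sample
# second-moment matrix, without reusing the package's profile formula
oracle_ppca_loglik <- function(X, k) {
  Xc <- sweep(X, 2L, colMeans(X))
  n <- ncol(Xc); Tn <- nrow(Xc)
  S <- crossprod(Xc) / Tn
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  sigma2 <- mean(lam[(k + 1):n])
  sigma2 <- max(sigma2, 1e-12)
  Wvar <- pmax(lam[seq_len(k)] - sigma2, 0)
  C <- e$vectors %*% diag(c(Wvar, rep(0, n - k)), n) %*% t(e$vectors) +
    sigma2 * diag(n)
  ei <- eigen(C, symmetric = TRUE)
  logdet <- sum(log(ei$values))
  Cinv <- ei$vectors %*% diag(1 / ei$values, n) %*% t(ei$vectors)
  -(Tn / 2) * (n * log(2 * pi) + logdet + sum(Cinv * S))
}

# exhaustive BIC over k with the oracle likelihood and the same
# parameter-count convention
oracle_select_k <- function(X, k_max) {
  Tn <- nrow(X); n <- ncol(X)
  # ML of pPCA uses the T-denominator likelihood; the package profiles the
  # (T-1)-denominator spectrum. Evaluate both on the same centered data so
  # the argmin comparison is meaningful.
  bic <- vapply(seq_len(k_max), function(k) {
    p <- n * k - k * (k - 1) / 2 + k + 1
    -2 * oracle_ppca_loglik(X, k) + p * log(Tn)
  }, numeric(1))
  which.min(bic)
}

# minimum-norm least squares through the normal equations and an explicit
# pseudoinverse (MASS::ginv) -- the independent route against fit_linear_map
oracle_lstsq <- function(X, Y) {
  MASS::ginv(X) %*% Y
}

# Gram-Schmidt: component of b orthogonal to a (and the intercept)
orthogonalize <- function(b, a) {
  a <- a - mean(a); b <- b - mean(b)
  b - a * sum(a * b) / sum(a * a)
}

expect_no_nan <- function(x) testthat::expect_false(any(is.nan(x)))

# end-to-end fixture: a coupled predictor region planted in a noisy volume,
# with the seed supplied as an external region
make_planted_volume <- function(rng_seed = 61, dims = c(10, 8, 4),
                                timepoints = 100, n_pred = 27, n_seed = 20,
                                placement = list(predictor = c(1, 1, 0),
                                                 seed = c(6, 4, 0))) {
  spec <- synthetic_spec(
    n_runs = 3, timepoints_per_run = timepoints,
    regions = list(predictor = list(n_voxels = n_pred, n_latent = 2),
                   seed = list(n_voxels = n_seed, n_latent = 2)),
    noise_sd = 0.5, rng_seed = rng_seed)
  ds <- generate_synthetic_dataset(spec)
  grid <- voxel_grid(dims)
  dir <- tempfile("vol")
  files <- write_as_volumes(ds, grid, placement = placement, dir = dir)
  list(ds = ds, files = files, grid = grid)
}

# compact variant on a 6 x 6 x 2 grid for the cheaper property tests
make_small_volume <- function(rng_seed, timepoints = 60) {
  make_planted_volume(rng_seed, dims = c(6, 6, 2), timepoints = timepoints,
                      n_pred = 8, n_seed = 8,
                      placement = list(predictor = c(0, 0, 0),
                                       seed = c(3, 3, 0)))
}
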