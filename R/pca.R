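#' Fit a region's representational space by PCA
#'
#' Singular value decomposition of the (column-centered) training matrix.
#' The loading columns (right singular vectors) define data-driven spatial
#' response patterns; the trajectory of the region through time is its
#' coordinate timecourse along those patterns. The training mean and
#' singular values are stored so that held-out runs can be projected into
#' the same space without re-estimating anything on test data.
#'
#' Loading-column signs are fixed deterministically (the largest-magnitude
#' element of each column is made positive) so results do not depend on the
#' SVD backend.
#'
#' @param train T x n numeric matrix of concatenated training runs, or a
#'   [timecourse_matrix()].
#' @param center Column-center before SVD (default `TRUE`). Centering is
#'   standard PCA and is required for the variance-explained reading of the
#'   singular values; a switch is kept for sensitivity checks.
#' @param k_max_ceiling Upper bound on the retained spectrum (default 50),
#'   capping searchlight cost.
#' @return An object of class `pca_basis` with elements `loadings`
#'   (n x k_max), `singular_values` (nonincreasing), `train_mean`, `k`
#'   (retained dimensionality; defaults to `k_max` until selected),
#'   `k_max` and `n_train_timepoints`.
#' @export
fit_pca <- function(train, center = TRUE, k_max_ceiling = 50) {
  if (inherits(train, "timecourse_matrix")) train <- train$values
  X <- as.matrix(train)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("training matrix must be finite", call. = FALSE)
  Tn <- nrow(X); n <- ncol(X)
  if (Tn < 2L) stop("need at least 2 training timepoints", call. = FALSE)
  mu <- if (center) colMeans(X) else rep(0, n)
  Xc <- sweep(X, 2L, mu)
  k_max <- min(n, Tn - 1L, as.integer(k_max_ceiling))
  k_max <- max(k_max, 1L)
  s <- svd(Xc, nu = 0, nv = k_max)
  V <- s$v
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(loadings = V, singular_values = s$d[seq_len(k_max)],
                 train_mean = mu, k = k_max, k_max = k_max,
                 n_voxels = n, n_train_timepoints = Tn,
                 centered = center),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf("<pca_basis> %d voxels, k = %d of k_max = %d (T_train = %d)\n",
              x$n_voxels, x$k, x$k_max, x$n_train_timepoints))
  invisible(x)
}

#' Set the retained dimensionality of a basis
#'
#' @param basis A [pca_basis()].
#' @param k Integer in `[1, k_max]`.
#' @return The basis with `k` set.
#' @export
set_k <- function(basis, k) {
  stopifnot(inherits(basis, "pca_basis"))
  k <- as.integer(k)
  if (k < 1L || k > basis$k_max)
    stop("`k` must lie in [1, k_max]", call. = FALSE)
  basis$k <- k
  basis
}

# covariance eigenvalues implied by the training singular values, padded
# with zeros to the full voxel dimension
pca_eigenvalues <- function(basis) {
  lam <- basis$singular_values^2 / (basis$n_train_timepoints - 1)
  c(lam, rep(0, basis$n_voxels - length(lam)))
}

# profile log-likelihood of a probabilistic PCA model with k signal
# dimensions and isotropic residual variance, at the ML estimates
ppca_loglik <- function(lambda, k, n_obs) {
  n <- length(lambda)
  sigma2 <- mean(lambda[(k + 1):n])
  sigma2 <- max(sigma2, 1e-12 * max(lambda, 1e-300))
  -(n_obs / 2) * (n * log(2 * pi) + sum(log(pmax(lambda[seq_len(k)], sigma2))) +
                    (n - k) * log(sigma2) + n)
}

#' Select dimensionality by BIC under a probabilistic-PCA model
#'
#' Evaluates, for each candidate k, the Gaussian log-likelihood of a
#' k-dimensional signal plus isotropic residual model at its maximum
#' (signal variances = the top k covariance eigenvalues, residual variance
#' = the mean of the rest) and penalizes with
#' `p(k) = n k - k (k - 1) / 2 + k + 1` parameters times `log(T)`.
#' Returns the k minimizing BIC, clamped to `[1, k_max]`.
#'
#' @param basis A [pca_basis()].
#' @return Integer k.
#' @export
select_k_bic <- function(basis) {
  stopifnot(inherits(basis, "pca_basis"))
  lam <- pca_eigenvalues(basis)
  n <- basis$n_voxels
  Tn <- basis$n_train_timepoints
  k_hi <- min(basis$k_max, n - 1L)
  if (k_hi < 1L) return(1L)
  bic <- vapply(seq_len(k_hi), function(k) {
    p <- n * k - k * (k - 1) / 2 + k + 1
    -2 * ppca_loglik(lam, k, Tn) + p * log(Tn)
  }, numeric(1))
  which.min(bic)
}

#' Project a run into a training-derived representational space
#'
#' Subtracts the training mean and multiplies by the first `k` loading
#' columns. The basis is never re-estimated on the projected (test) data.
#'
#' @param ts A [timecourse_matrix()] or plain T x n matrix with the basis's
#'   voxel count.
#' @param basis A [pca_basis()].
#' @param k Dimensionality (default `basis$k`).
#' @return An object of class `reduced_timecourse` with elements `values`
#'   (T x k), `basis` and `run_id`.
#' @export
project <- function(ts, basis, k = basis$k) {
  stopifnot(inherits(basis, "pca_basis"))
  run_id <- "run"
  if (inherits(ts, "timecourse_matrix")) {
    run_id <- ts$run_id
    ts <- ts$values
  }
  ts <- as.matrix(ts)
  if (ncol(ts) != basis$n_voxels)
    stop("column count does not match the basis dimension", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k > basis$k_max)
    stop("`k` must lie in [1, k_max]", call. = FALSE)
  vals <- sweep(ts, 2L, basis$train_mean) %*% basis$loadings[, seq_len(k), drop = FALSE]
  structure(list(values = vals, basis = basis, k = k, run_id = run_id),
            class = "reduced_timecourse")
}

#' Back-project a reduced prediction to voxel space
#'
#' Multiplies by the transposed loadings and re-adds the training mean
#' (the mean is re-added because centering was applied when the basis was
#' fit).
#'
#' @param reduced T x k matrix of reduced values.
#' @param basis The [pca_basis()] that defined the space.
#' @param k Dimensionality used.
#' @return T x n matrix of voxelwise values.
#' @export
back_project <- function(reduced, basis, k = ncol(as.matrix(reduced))) {
  reduced <- as.matrix(reduced)
  stopifnot(inherits(basis, "pca_basis"), ncol(reduced) == k)
  Vk <- basis$loadings[, seq_len(k), drop = FALSE]
  sweep(reduced %*% t(Vk), 2L, basis$train_mean, "+")
}

#' Serialize a PCA basis to a directory of TSV arrays
#'
#' Plain-text named-array container (loadings, singular_values, train_mean,
#' scalars) so bases can be exchanged without binary formats.
#'
#' @param basis A [pca_basis()].
#' @param dir Directory to create/write into.
#' @return `dir`, invisibly.
#' @export
write_pca_basis <- function(basis, dir) {
  stopifnot(inherits(basis, "pca_basis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(basis$loadings, file.path(dir, "loadings.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(basis$singular_values,
                     file.path(dir, "singular_values.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(basis$train_mean, file.path(dir, "train_mean.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(k = basis$k, k_max = basis$k_max,
                            n_voxels = basis$n_voxels,
                            n_train_timepoints = basis$n_train_timepoints,
                            centered = basis$centered),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_pca_basis
#' @export
read_pca_basis <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  structure(list(
    loadings = as.matrix(utils::read.delim(file.path(dir, "loadings.tsv"),
                                           header = FALSE)),
    singular_values = utils::read.delim(file.path(dir, "singular_values.tsv"),
                                        header = FALSE)[[1]],
    train_mean = utils::read.delim(file.path(dir, "train_mean.tsv"),
                                   header = FALSE)[[1]],
    k = as.integer(meta$k), k_max = as.integer(meta$k_max),
    n_voxels = as.integer(meta$n_voxels),
    n_train_timepoints = as.integer(meta$n_train_timepoints),
    centered = isTRUE(meta$centered)), class = "pca_basis")
}
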