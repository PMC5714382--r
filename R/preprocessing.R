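#' Nuisance regressor set
#'
#' A T x q matrix of nuisance timecourses (e.g. 5 CompCor components, the
#' global signal, 6 motion parameters) with column labels, for one run.
#'
#' @param regressors Numeric T x q matrix (q may be 0).
#' @param labels Character vector of q column labels.
#' @param run_id Run label.
#' @return An object of class `nuisance_set`.
#' @export
nuisance_set <- function(regressors, labels = NULL, run_id = "run1") {
  regressors <- as.matrix(regressors)
  storage.mode(regressors) <- "double"
  if (ncol(regressors) > 0L && !all(is.finite(regressors)))
    stop("nuisance regressors must be finite", call. = FALSE)
  if (is.null(labels)) {
    labels <- if (ncol(regressors) > 0L) {
      cn <- colnames(regressors)
      if (is.null(cn)) paste0("nuis", seq_len(ncol(regressors))) else cn
    } else character(0)
  }
  if (length(labels) != ncol(regressors))
    stop("need one label per regressor column", call. = FALSE)
  colnames(regressors) <- labels
  structure(list(regressors = regressors, labels = labels,
                 run_id = as.character(run_id)), class = "nuisance_set")
}

#' Combine nuisance sets column-wise
#'
#' @param ... `nuisance_set` objects for the same run.
#' @return A single [nuisance_set()].
#' @export
combine_nuisance <- function(...) {
  sets <- list(...)
  stopifnot(all(vapply(sets, inherits, logical(1), "nuisance_set")))
  nuisance_set(do.call(cbind, lapply(sets, `[[`, "regressors")),
               labels = unlist(lapply(sets, `[[`, "labels")),
               run_id = sets[[1]]$run_id)
}

#' Read a nuisance table from delimited text
#'
#' @param path TSV path with a header row of labels.
#' @param run_id Run label.
#' @return A [nuisance_set()].
#' @export
read_nuisance_tsv <- function(path, run_id = "run1") {
  df <- utils::read.delim(path)
  nuisance_set(as.matrix(df), labels = names(df), run_id = run_id)
}

#' Censoring vector for one run
#'
#' Externally supplied outlier flags (e.g. from ART): `TRUE` keeps a
#' timepoint, `FALSE` drops it. Outlier thresholds themselves are
#' experimenter-defined upstream and are not reimplemented here.
#'
#' @param keep Logical (or 0/1) vector; at least 2 timepoints must be kept.
#' @param run_id Run label.
#' @return An object of class `censor_vector`.
#' @export
censor_vector <- function(keep, run_id = "run1") {
  keep <- as.logical(keep)
  if (any(is.na(keep))) stop("`keep` must be TRUE/FALSE", call. = FALSE)
  if (sum(keep) < 2L)
    stop("censoring must retain at least 2 timepoints", call. = FALSE)
  structure(list(keep = keep, run_id = as.character(run_id)),
            class = "censor_vector")
}

#' @rdname censor_vector
#' @param path TSV path holding a single column of 0/1 flags.
#' @export
read_censor_tsv <- function(path, run_id = "run1") {
  v <- utils::read.delim(path)[[1]]
  censor_vector(v != 0, run_id = run_id)
}

# SPM-style discrete-cosine drift basis: constant + cosines with period
# >= cutoff_s. Columns are orthonormal on the T-point grid.
dct_drift_basis <- function(n_timepoints, tr_s, cutoff_s) {
  k_max <- floor(2 * n_timepoints * tr_s / cutoff_s)
  t0 <- seq_len(n_timepoints) - 1L
  cols <- lapply(0:k_max, function(k) {
    if (k == 0L) rep(1 / sqrt(n_timepoints), n_timepoints)
    else sqrt(2 / n_timepoints) * cos(pi * (2 * t0 + 1) * k / (2 * n_timepoints))
  })
  do.call(cbind, cols)
}

#' High-pass filter by discrete-cosine drift removal
#'
#' Removes, per voxel, the subspace spanned by a discrete-cosine drift basis
#' whose periods are at least `cutoff_s` seconds (constant term included),
#' the convention used for slow-drift removal in fMRI GLM software. The
#' output is exactly orthogonal to the drift basis, and the operation is
#' idempotent.
#'
#' @param ts A [timecourse_matrix()].
#' @param cutoff_s Cutoff period in seconds (default 128); must exceed
#'   twice the repetition time.
#' @return A filtered [timecourse_matrix()].
#' @export
highpass_filter <- function(ts, cutoff_s = 128) {
  stopifnot(inherits(ts, "timecourse_matrix"))
  if (!is.numeric(cutoff_s) || cutoff_s <= 2 * ts$tr_s)
    stop("`cutoff_s` must exceed twice the repetition time", call. = FALSE)
  X <- dct_drift_basis(nrow(ts$values), ts$tr_s, cutoff_s)
  # orthonormal columns: projection is X (X'Y)
  resid <- ts$values - X %*% crossprod(X, ts$values)
  timecourse_matrix(resid, tr_s = ts$tr_s, run_id = ts$run_id,
                    voxel_order = ts$voxel_order)
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward and backward
#' ([signal::filtfilt()]), so low-frequency content is not shifted in time.
#' Used on region-mean timecourses for standard functional connectivity
#' (default cutoff 0.1 Hz).
#'
#' @param ts A [timecourse_matrix()].
#' @param cutoff_hz Cutoff frequency in Hz; must be below the Nyquist
#'   frequency `1 / (2 tr_s)`.
#' @param order Butterworth order (default 4).
#' @return A filtered [timecourse_matrix()].
#' @export
lowpass_filter <- function(ts, cutoff_hz = 0.1, order = 4) {
  stopifnot(inherits(ts, "timecourse_matrix"))
  nyq <- 1 / (2 * ts$tr_s)
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyq)
    stop("`cutoff_hz` must lie in (0, Nyquist)", call. = FALSE)
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  # filtfilt is DC-neutral up to edge effects; remove/restore the mean so a
  # constant column passes through unchanged
  mu <- colMeans(ts$values)
  vals <- apply(sweep(ts$values, 2L, mu), 2L,
                function(col) signal::filtfilt(bf, col))
  vals <- sweep(matrix(vals, nrow = nrow(ts$values)), 2L, mu, "+")
  timecourse_matrix(vals, tr_s = ts$tr_s, run_id = ts$run_id,
                    voxel_order = ts$voxel_order)
}

#' CompCor noise components from a control region
#'
#' Principal-component timecourses of the column-centered control-region
#' matrix (white matter + CSF voxels): since the control region contains no
#' gray matter, its dominant components are taken to reflect noise, and are
#' later regressed out of gray-matter timecourses.
#'
#' @param control_ts [timecourse_matrix()] of the control region.
#' @param n_components Number of components (default 5).
#' @return A [nuisance_set()] of unit-norm, mutually orthogonal component
#'   timecourses.
#' @export
compcor_components <- function(control_ts, n_components = 5) {
  stopifnot(inherits(control_ts, "timecourse_matrix"))
  X <- control_ts$values
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(nrow(X) - 1L, ncol(X)))
    stop("`n_components` must be in [1, min(T - 1, voxels)]", call. = FALSE)
  Xc <- sweep(X, 2L, colMeans(X))
  s <- svd(Xc, nu = n_components, nv = 0)
  if (s$d[1] <= 1e-12 * sqrt(length(Xc)))
    stop("control region has no variance; cannot extract components",
         call. = FALSE)
  if (s$d[n_components] <= 1e-12 * s$d[1])
    warning("requested CompCor components include zero-variance directions")
  U <- s$u
  # sign convention: largest-|.| element positive
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  nuisance_set(U, labels = paste0("compcor", seq_len(n_components)),
               run_id = control_ts$run_id)
}

#' Regress nuisance timecourses out of a region
#'
#' Per voxel, the OLS residual after regressing on an intercept plus the
#' nuisance columns. Residuals are exactly orthogonal to every nuisance
#' column; rank-deficient nuisance sets are handled by pivoted QR (the
#' projection is still well defined) with a warning.
#'
#' @param ts A [timecourse_matrix()].
#' @param nuisance A [nuisance_set()] with matching row count (q = 0 yields
#'   plain column demeaning).
#' @return A residual [timecourse_matrix()].
#' @export
regress_out <- function(ts, nuisance) {
  stopifnot(inherits(ts, "timecourse_matrix"),
            inherits(nuisance, "nuisance_set"))
  q <- ncol(nuisance$regressors)
  if (q > 0L && nrow(nuisance$regressors) != nrow(ts$values))
    stop("nuisance row count does not match the run", call. = FALSE)
  X <- cbind(intercept = 1, nuisance$regressors)
  fit <- stats::lm.fit(X, ts$values)
  if (fit$rank < ncol(X))
    warning("rank-deficient nuisance set; projecting onto its column space")
  timecourse_matrix(as.matrix(fit$residuals), tr_s = ts$tr_s,
                    run_id = ts$run_id, voxel_order = ts$voxel_order)
}

#' Drop censored timepoints
#'
#' @param ts A [timecourse_matrix()].
#' @param censor A [censor_vector()] of the same length as the run.
#' @return A [timecourse_matrix()] with the flagged rows removed.
#' @export
apply_censor <- function(ts, censor) {
  stopifnot(inherits(ts, "timecourse_matrix"),
            inherits(censor, "censor_vector"))
  if (length(censor$keep) != nrow(ts$values))
    stop("censor length does not match the run", call. = FALSE)
  timecourse_matrix(ts$values[censor$keep, , drop = FALSE], tr_s = ts$tr_s,
                    run_id = ts$run_id, voxel_order = ts$voxel_order)
}

#' Remove the univariate (spatial-mean) signal
#'
#' Subtracts, at every timepoint, the mean across voxels, so every row of
#' the result sums to zero. After this step the region's mean timecourse is
#' identically zero and only spatial patterns remain, making any subsequent
#' analysis fully complementary to mean-based functional connectivity.
#'
#' @param ts A [timecourse_matrix()] with at least 2 voxels.
#' @return A [timecourse_matrix()] with zero spatial mean at each timepoint.
#' @export
remove_univariate_signal <- function(ts) {
  stopifnot(inherits(ts, "timecourse_matrix"))
  if (ncol(ts$values) < 2L)
    stop("univariate-signal removal needs at least 2 voxels", call. = FALSE)
  vals <- ts$values - rowMeans(ts$values)
  timecourse_matrix(vals, tr_s = ts$tr_s, run_id = ts$run_id,
                    voxel_order = ts$voxel_order)
}
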