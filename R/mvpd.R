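#' Configuration for cross-validated MVPD
#'
#' @param component_mode `"bic"` selects each region's dimensionality per
#'   fold with [select_k_bic()]; `"fixed"` uses `k_fixed` components for
#'   both regions (the incremental-contribution analysis uses fixed k of 1,
#'   2 and 3).
#' @param k_fixed Dimensionality in fixed mode (default 3).
#' @param k_max Ceiling on the retained spectrum (default 50).
#' @param weights `"singular"` weights dimension correlations by the
#'   training singular values as printed in the defining formula;
#'   `"variance"` squares them (proportion-of-variance weighting).
#' @param center Column-center training data before the SVD (default TRUE).
#' @param remove_univariate Remove the spatial-mean signal from both
#'   regions before analysis, making the result fully complementary to
#'   mean-based functional connectivity.
#' @return A list of class `mvpd_config`.
#' @export
mvpd_config <- function(component_mode = c("bic", "fixed"), k_fixed = 3,
                        k_max = 50, weights = c("singular", "variance"),
                        center = TRUE, remove_univariate = FALSE) {
  component_mode <- match.arg(component_mode)
  weights <- match.arg(weights)
  k_fixed <- as.integer(k_fixed)
  if (k_fixed < 1L) stop("`k_fixed` must be >= 1", call. = FALSE)
  structure(list(component_mode = component_mode, k_fixed = k_fixed,
                 k_max = as.integer(k_max), weights = weights,
                 center = isTRUE(center),
                 remove_univariate = isTRUE(remove_univariate)),
            class = "mvpd_config")
}

#' Ordinary-least-squares map between representational spaces
#'
#' Fits the coefficient matrix B minimizing `||Y - X B||_F^2` for reduced
#' timecourses X (T x k_X, predictor region) and Y (T x k_Y, seed region),
#' via the SVD-based minimum-norm solution (well defined for rank-deficient
#' X). Residuals are orthogonal to the columns of X.
#'
#' @param x,y [project()] outputs or plain matrices with equal row counts.
#' @param fold_id Label of the left-out run this fold excludes.
#' @return An object of class `mvpd_linear_map` with elements
#'   `coefficients` (k_X x k_Y), `train_residual_ss` (per seed dimension)
#'   and `fold_id`.
#' @export
fit_linear_map <- function(x, y, fold_id = NA_character_) {
  X <- if (inherits(x, "reduced_timecourse")) x$values else as.matrix(x)
  Y <- if (inherits(y, "reduced_timecourse")) y$values else as.matrix(y)
  if (nrow(X) != nrow(Y))
    stop("predictor and seed must have equal row counts", call. = FALSE)
  if (nrow(X) <= ncol(X))
    warning("T <= k_X: underdetermined fit; returning the minimum-norm solution")
  s <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(s$d, 0)
  r <- sum(s$d > tol)
  B <- if (r == 0L) {
    matrix(0, ncol(X), ncol(Y))
  } else {
    s$v[, seq_len(r), drop = FALSE] %*%
      ((1 / s$d[seq_len(r)]) * crossprod(s$u[, seq_len(r), drop = FALSE], Y))
  }
  structure(list(coefficients = B,
                 train_residual_ss = colSums((Y - X %*% B)^2),
                 fold_id = fold_id),
            class = "mvpd_linear_map")
}

#' Predict a held-out run's seed trajectory
#'
#' Applies a trained [fit_linear_map()] to the predictor region's reduced
#' test timecourse, and optionally back-projects the prediction to voxel
#' space through the seed basis.
#'
#' @param map An `mvpd_linear_map`.
#' @param x_test Reduced predictor timecourse for the left-out run (T x
#'   k_X).
#' @param y_basis Optional seed [pca_basis()]; when given, the voxelwise
#'   prediction is included.
#' @param k_y Seed dimensionality used for back-projection.
#' @return An object of class `prediction_bundle` with
#'   `reduced_prediction` (T x k_Y), `voxel_prediction` (T x n_Y or NULL)
#'   and `method = "mvpd"`.
#' @export
predict_timecourse <- function(map, x_test, y_basis = NULL,
                               k_y = if (is.null(y_basis)) NULL else y_basis$k) {
  stopifnot(inherits(map, "mvpd_linear_map"))
  X <- if (inherits(x_test, "reduced_timecourse")) x_test$values else as.matrix(x_test)
  if (ncol(X) != nrow(map$coefficients))
    stop("x_test column count does not match the fitted map", call. = FALSE)
  red <- X %*% map$coefficients
  vox <- NULL
  if (!is.null(y_basis)) {
    if (ncol(red) != k_y)
      stop("map output dimension does not match `k_y`", call. = FALSE)
    vox <- back_project(red, y_basis, k_y)
  }
  structure(list(reduced_prediction = red, voxel_prediction = vox,
                 method = "mvpd"), class = "prediction_bundle")
}

#' Per-dimension prediction correlations
#'
#' Pearson correlation between predicted and observed timecourses for each
#' seed dimension. A constant predicted or observed dimension has an
#' undefined correlation; it is reported as 0 with a warning (conservative:
#' keeps the weighted summary defined).
#'
#' @param pred A `prediction_bundle` or T x k matrix of predictions.
#' @param y_test Observed reduced seed timecourse (same shape).
#' @return Numeric vector of length k_Y, each in `[-1, 1]`.
#' @export
dimension_correlations <- function(pred, y_test) {
  P <- if (inherits(pred, "prediction_bundle")) pred$reduced_prediction
       else as.matrix(pred)
  Y <- if (inherits(y_test, "reduced_timecourse")) y_test$values
       else as.matrix(y_test)
  if (!all(dim(P) == dim(Y)))
    stop("prediction and observation shapes differ", call. = FALSE)
  if (nrow(P) < 3L)
    stop("need at least 3 timepoints for a correlation", call. = FALSE)
  vapply(seq_len(ncol(P)), function(j) safe_cor(P[, j], Y[, j]), numeric(1))
}

safe_cor <- function(a, b) {
  sda <- stats::sd(a); sdb <- stats::sd(b)
  if (!is.finite(sda) || !is.finite(sdb) || sda == 0 || sdb == 0) {
    warning("constant timecourse in correlation; reporting r = 0")
    return(0)
  }
  stats::cor(a, b)
}

# per-dimension weights from the training spectrum
dependence_weights <- function(basis, k = basis$k,
                               mode = c("singular", "variance")) {
  mode <- match.arg(mode)
  s <- basis$singular_values[seq_len(k)]
  if (mode == "variance") s <- s^2
  tot <- sum(s)
  if (tot <= 0) stop("all singular values are zero", call. = FALSE)
  s / tot
}

#' Variance-weighted dependence summary
#'
#' Averages the per-dimension correlations weighted by the share of each
#' dimension in the seed's training spectrum:
#' `w_j = S(j,j) / sum_l S(l,l)` with S the training singular values (the
#' `"variance"` mode uses squared singular values instead).
#'
#' @param r Per-dimension correlations (length `k`).
#' @param basis Seed [pca_basis()] providing the training spectrum.
#' @param k Dimensionality (default `length(r)`).
#' @param mode `"singular"` (default) or `"variance"`.
#' @return The scalar weighted mean, in `[-1, 1]`.
#' @export
weighted_dependence <- function(r, basis, k = length(r),
                                mode = c("singular", "variance")) {
  stopifnot(inherits(basis, "pca_basis"))
  if (length(r) != k)
    stop("`r` length must equal the retained dimensionality", call. = FALSE)
  w <- dependence_weights(basis, k, match.arg(mode))
  sum(w * r)
}

#' Voxelwise cross-validated variance explained
#'
#' `v(j) = 1 - SS(Y(:,j) - Yhat(:,j)) / SS(Y(:,j))` with SS the raw
#' (uncentered) sum of squares, per seed voxel, plus the across-voxel mean
#' `v_bar`. Values can be negative (prediction worse than zero); a voxel
#' with zero total SS gets v = 0 with a warning.
#'
#' @param pred A `prediction_bundle` with a voxel prediction, or a T x n
#'   matrix.
#' @param y_test_voxels Observed voxel timecourses (T x n matrix or
#'   [timecourse_matrix()]).
#' @return List with `v_per_voxel` and `v_bar`.
#' @export
voxelwise_r2 <- function(pred, y_test_voxels) {
  P <- if (inherits(pred, "prediction_bundle")) pred$voxel_prediction
       else as.matrix(pred)
  if (is.null(P)) stop("prediction bundle has no voxel prediction", call. = FALSE)
  Y <- if (inherits(y_test_voxels, "timecourse_matrix")) y_test_voxels$values
       else as.matrix(y_test_voxels)
  if (!all(dim(P) == dim(Y)))
    stop("prediction and observation shapes differ", call. = FALSE)
  ss_tot <- colSums(Y^2)
  ss_res <- colSums((Y - P)^2)
  v <- 1 - ss_res / ss_tot
  bad <- ss_tot == 0
  if (any(bad)) {
    warning("zero-variance voxel(s): reporting v = 0")
    v[bad] <- 0
  }
  list(v_per_voxel = v, v_bar = mean(v))
}

# one leave-one-run-out fold of MVPD
mvpd_fold <- function(seed, predictor, fold, cfg) {
  y_train <- rs_concat(seed, exclude = fold)
  x_train <- rs_concat(predictor, exclude = fold)
  y_test <- seed$runs[[fold]]$values
  x_test <- predictor$runs[[fold]]$values

  by <- fit_pca(y_train, center = cfg$center, k_max_ceiling = cfg$k_max)
  bx <- fit_pca(x_train, center = cfg$center, k_max_ceiling = cfg$k_max)
  if (cfg$component_mode == "bic") {
    by <- set_k(by, select_k_bic(by))
    bx <- set_k(bx, select_k_bic(bx))
  } else {
    by <- set_k(by, min(cfg$k_fixed, by$k_max))
    bx <- set_k(bx, min(cfg$k_fixed, bx$k_max))
  }
  map <- fit_linear_map(project(x_train, bx), project(y_train, by),
                        fold_id = seed$runs[[fold]]$run_id)
  bundle <- predict_timecourse(map, project(x_test, bx), y_basis = by)
  r <- dimension_correlations(bundle, project(y_test, by))
  w <- dependence_weights(by, by$k, cfg$weights)
  vr <- voxelwise_r2(bundle, y_test)
  list(fold = fold, run_id = seed$runs[[fold]]$run_id,
       k_y = by$k, k_x = bx$k, r_per_dim = r, weights = w,
       r_bar = sum(w * r), v_per_voxel = vr$v_per_voxel, v_bar = vr$v_bar)
}

#' Cross-validated multivariate pattern dependence
#'
#' The full leave-one-run-out procedure: for each fold, the remaining runs
#' are concatenated, both regions' representational spaces are estimated,
#' the linear map from predictor to seed dimensions is fit by OLS, the
#' left-out run is predicted, and per-dimension correlations, their
#' weighted summary and the voxelwise cross-validated variance explained
#' are computed. Fold summaries are averaged (unweighted) into `r_bar` and
#' `v_bar`.
#'
#' @param seed [run_set()] of the seed (target) region.
#' @param predictor [run_set()] of the predictor region.
#' @param config An [mvpd_config()].
#' @return An object of class `mvpd_result` with per-fold detail
#'   (`folds`), `r_bar_per_fold`, `r_bar`, `v_per_voxel` (fold-averaged),
#'   `v_bar` and `method = "mvpd"`.
#' @export
crossvalidated_mvpd <- function(seed, predictor, config = mvpd_config()) {
  stopifnot(inherits(seed, "run_set"), inherits(predictor, "run_set"))
  if (seed$m != predictor$m)
    stop("seed and predictor must have the same number of runs", call. = FALSE)
  tl <- vapply(seed$runs, function(r) nrow(r$values), integer(1))
  tlp <- vapply(predictor$runs, function(r) nrow(r$values), integer(1))
  if (!all(tl == tlp))
    stop("seed and predictor run lengths are misaligned", call. = FALSE)
  if (config$remove_univariate) {
    seed <- rs_map(seed, remove_univariate_signal)
    predictor <- rs_map(predictor, remove_univariate_signal)
  }
  folds <- lapply(seq_len(seed$m), function(i)
    mvpd_fold(seed, predictor, i, config))
  r_bar_per_fold <- vapply(folds, `[[`, numeric(1), "r_bar")
  v_mat <- do.call(rbind, lapply(folds, `[[`, "v_per_voxel"))
  structure(list(folds = folds, r_bar_per_fold = r_bar_per_fold,
                 r_bar = mean(r_bar_per_fold),
                 v_per_voxel = colMeans(v_mat),
                 v_bar = mean(vapply(folds, `[[`, numeric(1), "v_bar")),
                 method = "mvpd", config = config),
            class = "mvpd_result")
}

#' @export
print.mvpd_result <- function(x, ...) {
  cat(sprintf("<mvpd_result> method '%s': r_bar = %.4f, v_bar = %.4f over %d folds\n",
              x$method, x$r_bar, x$v_bar, length(x$r_bar_per_fold)))
  invisible(x)
}

#' Serialize a dependence result
#'
#' Writes a per-fold TSV table (fold, dimension, r_j, w_j, r_bar_i) and a
#' JSON summary (r_bar, v_bar, method).
#'
#' @param result An `mvpd_result`.
#' @param tsv_path,json_path Output paths (either may be NULL to skip).
#' @return Invisibly, a list of the paths written.
#' @export
write_dependence_result <- function(result, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "mvpd_result"))
  if (!is.null(tsv_path)) {
    rows <- do.call(rbind, lapply(result$folds, function(f) {
      k <- length(f$r_per_dim)
      data.frame(fold = f$fold, run_id = f$run_id, j = seq_len(k),
                 r_j = f$r_per_dim, w_j = f$weights, r_bar_i = f$r_bar)
    }))
    utils::write.table(rows, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(method = result$method, r_bar = result$r_bar,
                              v_bar = result$v_bar,
                              r_bar_per_fold = result$r_bar_per_fold),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(tsv = tsv_path, json = json_path))
}
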