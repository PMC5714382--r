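#' Standard functional connectivity
#'
#' The classical seed-based measure: the spatial-mean timecourse of each
#' region is low-pass filtered per run (default 0.1 Hz, zero-phase
#' Butterworth), runs are concatenated, and the Pearson correlation between
#' the two filtered means is returned. Because it uses only the spatial
#' means, this measure is blind to any dependence carried purely by
#' zero-mean spatial patterns.
#'
#' @param seed,predictor [run_set()]s with aligned runs.
#' @param cutoff_hz Low-pass cutoff in Hz (default 0.1).
#' @param combine `"concat"` (default) correlates the concatenated
#'   filtered means; `"fisher"` computes per-run correlations and averages
#'   them on the Fisher-z scale.
#' @return An object of class `fc_result` with `r`, `r_per_run` and
#'   `method = "standard_fc"`.
#' @export
standard_fc <- function(seed, predictor, cutoff_hz = 0.1,
                        combine = c("concat", "fisher")) {
  stopifnot(inherits(seed, "run_set"), inherits(predictor, "run_set"))
  combine <- match.arg(combine)
  if (seed$m != predictor$m)
    stop("seed and predictor must have the same number of runs", call. = FALSE)
  filt_mean <- function(run) {
    mu <- rowMeans(run$values)
    # a mean timecourse carrying none of the region's variance (exactly
    # constant, or pure floating-point residue after univariate-signal
    # removal) is degenerate: its correlation is defined as 0
    degenerate <- stats::sd(mu) <= 1e-10 * max(stats::sd(run$values), 1e-300)
    tc <- timecourse_matrix(matrix(mu, ncol = 1), tr_s = run$tr_s,
                            run_id = run$run_id)
    list(values = lowpass_filter(tc, cutoff_hz)$values[, 1],
         degenerate = degenerate)
  }
  s_means <- lapply(seed$runs, filt_mean)
  p_means <- lapply(predictor$runs, filt_mean)
  degenerate <- any(vapply(c(s_means, p_means), `[[`, logical(1), "degenerate"))
  s_means <- lapply(s_means, `[[`, "values")
  p_means <- lapply(p_means, `[[`, "values")
  if (any(lengths(s_means) != lengths(p_means)))
    stop("seed and predictor run lengths are misaligned", call. = FALSE)
  if (degenerate) {
    warning("constant mean timecourse; reporting r = 0")
    r_per_run <- rep(0, seed$m)
    r <- 0
  } else {
    r_per_run <- mapply(function(a, b) suppressWarnings(safe_cor(a, b)),
                        s_means, p_means)
    r <- if (combine == "concat") {
      stats::cor(unlist(s_means), unlist(p_means))
    } else {
      z <- atanh(pmin(pmax(r_per_run, -1 + 1e-12), 1 - 1e-12))
      tanh(mean(z))
    }
  }
  structure(list(r = r, r_per_run = r_per_run, method = "standard_fc",
                 cutoff_hz = cutoff_hz, combine = combine),
            class = "fc_result")
}

#' @export
print.fc_result <- function(x, ...) {
  cat(sprintf("<fc_result> method '%s': r = %.4f over %d runs\n",
              x$method, x$r, length(x$r_per_run)))
  invisible(x)
}

#' Leave-one-out univariate dependence
#'
#' Mean-based functional connectivity recast as a cross-validated
#' prediction, so its variance explained is directly comparable to MVPD's:
#' per fold, the seed's spatial-mean timecourse is regressed (slope +
#' intercept) on the predictor's over the training runs; the left-out
#' run's seed mean is predicted; and every seed voxel is predicted by that
#' predicted mean — the mean is treated as a single dimension with equal
#' loadings on all voxels.
#'
#' @param seed,predictor [run_set()]s with aligned runs (m >= 2).
#' @return An `mvpd_result` with `method = "loo_univariate"`: per-fold
#'   correlation between predicted and observed seed mean (`r_bar_per_fold`,
#'   averaged into `r_bar`), plus voxelwise `v_per_voxel` / `v_bar`.
#' @export
loo_univariate <- function(seed, predictor) {
  stopifnot(inherits(seed, "run_set"), inherits(predictor, "run_set"))
  if (seed$m != predictor$m)
    stop("seed and predictor must have the same number of runs", call. = FALSE)
  folds <- lapply(seq_len(seed$m), function(i) {
    y_tr <- rowMeans(rs_concat(seed, exclude = i))
    x_tr <- rowMeans(rs_concat(predictor, exclude = i))
    x_te <- rowMeans(predictor$runs[[i]]$values)
    y_te_vox <- seed$runs[[i]]$values
    y_te <- rowMeans(y_te_vox)
    if (stats::sd(x_tr) == 0) {
      warning("constant predictor mean in training; predicting the intercept only")
      beta <- c(mean(y_tr), 0)
    } else {
      beta <- stats::coef(stats::lm.fit(cbind(1, x_tr), y_tr))
    }
    y_hat <- beta[1] + beta[2] * x_te
    r_i <- suppressWarnings(safe_cor(y_hat, y_te))
    vox_pred <- matrix(y_hat, nrow = length(y_hat),
                       ncol = ncol(y_te_vox))
    vr <- voxelwise_r2(vox_pred, y_te_vox)
    list(fold = i, run_id = seed$runs[[i]]$run_id, k_y = 1L, k_x = 1L,
         r_per_dim = r_i, weights = 1, r_bar = r_i,
         v_per_voxel = vr$v_per_voxel, v_bar = vr$v_bar)
  })
  r_bar_per_fold <- vapply(folds, `[[`, numeric(1), "r_bar")
  v_mat <- do.call(rbind, lapply(folds, `[[`, "v_per_voxel"))
  structure(list(folds = folds, r_bar_per_fold = r_bar_per_fold,
                 r_bar = mean(r_bar_per_fold),
                 v_per_voxel = colMeans(v_mat),
                 v_bar = mean(vapply(folds, `[[`, numeric(1), "v_bar")),
                 method = "loo_univariate", config = NULL),
            class = "mvpd_result")
}
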