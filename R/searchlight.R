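#' Searchlight configuration
#'
#' @param radius_mm Sphere radius in millimetres (default 6).
#' @param metric One of `"mvpd_rbar"` (weighted dependence summary),
#'   `"mvpd_v"` (voxelwise cross-validated variance explained, averaged
#'   over seed voxels), `"fc"` (standard functional connectivity),
#'   `"loo_univariate"` (cross-validated mean-based dependence) or
#'   `"mvpd_rbar_per_dim"` (one map per seed dimension).
#' @param component_mode `"fixed"` or `"bic"`. Per-dimension maps require
#'   fixed k: BIC would change k from sphere to sphere, destroying the
#'   identity of "dimension j" across the brain (k is a property of the
#'   seed and is held fixed).
#' @param k_fixed Dimensionality in fixed mode (default 3).
#' @param k_max Spectrum ceiling (default 50).
#' @param weights `"singular"` or `"variance"` (see [mvpd_config()]).
#' @param remove_univariate Remove each region's spatial-mean signal first.
#' @param exclude_seed Drop seed-ROI voxels from every sphere
#'   (self-prediction inflates dependence near the seed); default `FALSE`,
#'   spheres overlapping the seed are computed as-is.
#' @param swap_roles Use the seed as predictor and the sphere as target
#'   (default `FALSE`: the sphere predicts the seed).
#' @param fc_cutoff_hz Low-pass cutoff for the `"fc"` metric.
#' @return A list of class `searchlight_config`.
#' @export
searchlight_config <- function(radius_mm = 6,
                               metric = c("mvpd_rbar", "mvpd_v", "fc",
                                          "loo_univariate",
                                          "mvpd_rbar_per_dim"),
                               component_mode = c("fixed", "bic"),
                               k_fixed = 3, k_max = 50,
                               weights = c("singular", "variance"),
                               remove_univariate = FALSE,
                               exclude_seed = FALSE, swap_roles = FALSE,
                               fc_cutoff_hz = 0.1) {
  metric <- match.arg(metric)
  component_mode <- match.arg(component_mode)
  if (!is.numeric(radius_mm) || radius_mm <= 0)
    stop("`radius_mm` must be positive", call. = FALSE)
  if (metric == "mvpd_rbar_per_dim" && component_mode != "fixed")
    stop("per-dimension maps require fixed-k mode", call. = FALSE)
  structure(list(radius_mm = radius_mm, metric = metric,
                 component_mode = component_mode,
                 k_fixed = as.integer(k_fixed), k_max = as.integer(k_max),
                 weights = match.arg(weights),
                 remove_univariate = isTRUE(remove_univariate),
                 exclude_seed = isTRUE(exclude_seed),
                 swap_roles = isTRUE(swap_roles),
                 fc_cutoff_hz = fc_cutoff_hz),
            class = "searchlight_config")
}

# Extract a run_set over `mask` from a list of 4D volumes (arrays or paths)
runs_to_runset <- function(runs, mask, tr_s) {
  mats <- lapply(seq_along(runs), function(i)
    load_run_timecourses(runs[[i]], mask, tr_s,
                         run_id = paste0("run", i)))
  run_set(mats)
}

#' Sweep a searchlight sphere over a gray-matter mask
#'
#' For every voxel of `gm_mask`, a sphere of `cfg$radius_mm` is drawn
#' (restricted to the mask), its timecourses are extracted, and the
#' configured dependence metric between the sphere (predictor) and the
#' fixed seed region (target) is computed. Sphere computations are
#' independent; the result does not depend on traversal order.
#'
#' @param runs List of per-run 4D volumes (arrays or NIfTI paths), all on
#'   `gm_mask`'s grid.
#' @param gm_mask [voxel_mask()] of analyzed voxels.
#' @param seed Either a [voxel_mask()] on the same grid (seed timecourses
#'   are extracted from `runs`) or an external [run_set()] of seed
#'   timecourses.
#' @param cfg A [searchlight_config()].
#' @param tr_s Repetition time in seconds.
#' @return A [brain_map()] over `gm_mask`, or a list of k maps for
#'   `metric = "mvpd_rbar_per_dim"`. Spheres that end up empty yield NaN.
#' @export
run_searchlight <- function(runs, gm_mask, seed, cfg = searchlight_config(),
                            tr_s = 2) {
  stopifnot(inherits(gm_mask, "voxel_mask"),
            inherits(cfg, "searchlight_config"))
  gm_rs <- runs_to_runset(runs, gm_mask, tr_s)
  if (inherits(seed, "voxel_mask")) {
    if (!grids_equal(seed$grid, gm_mask$grid))
      stop("seed mask and gray-matter mask are on different grids",
           call. = FALSE)
    seed_rs <- runs_to_runset(runs, seed, tr_s)
    seed_lin <- mask_linear_index(seed)
  } else if (inherits(seed, "run_set")) {
    seed_rs <- seed
    seed_lin <- integer(0)
  } else stop("`seed` must be a voxel_mask or a run_set", call. = FALSE)
  if (seed_rs$m != gm_rs$m)
    stop("seed and volume run counts differ", call. = FALSE)
  if (cfg$remove_univariate) seed_rs <- rs_map(seed_rs, remove_univariate_signal)

  grid <- gm_mask$grid
  d <- grid$dims
  gm_lin <- mask_linear_index(gm_mask)
  col_of <- rep(NA_integer_, prod(d))
  col_of[gm_lin] <- seq_along(gm_lin)
  off <- sphere_offsets(cfg$radius_mm, grid)
  nvox <- length(gm_mask)
  vi <- gm_mask$voxel_indices

  seed_ctx <- searchlight_seed_context(seed_rs, cfg)
  k_y <- seed_ctx$k_y
  per_dim <- cfg$metric == "mvpd_rbar_per_dim"
  out <- if (per_dim) matrix(NaN, nvox, k_y) else rep(NaN, nvox)

  m <- gm_rs$m
  gm_mats <- lapply(gm_rs$runs, `[[`, "values")
  for (v in seq_len(nvox)) {
    cand <- sweep(off, 2L, vi[v, ], "+")
    ok <- cand[, 1] >= 0L & cand[, 1] < d[1] &
      cand[, 2] >= 0L & cand[, 2] < d[2] &
      cand[, 3] >= 0L & cand[, 3] < d[3]
    lin <- 1 + cand[ok, 1] + d[1] * (cand[ok, 2] + d[2] * cand[ok, 3])
    if (cfg$exclude_seed && length(seed_lin))
      lin <- setdiff(lin, seed_lin)
    cols <- col_of[lin]
    cols <- sort(cols[!is.na(cols)])
    if (length(cols) == 0L) next
    sphere_mats <- lapply(gm_mats, function(mmat) mmat[, cols, drop = FALSE])
    val <- tryCatch(
      searchlight_metric(sphere_mats, seed_ctx, cfg, tr_s),
      error = function(e) NULL)
    if (is.null(val)) next
    if (per_dim) out[v, ] <- val else out[v] <- val
  }
  if (per_dim) {
    lapply(seq_len(k_y), function(j)
      brain_map(gm_mask, out[, j],
                label = sprintf("%s_dim%d", cfg$metric, j)))
  } else {
    brain_map(gm_mask, out, label = cfg$metric)
  }
}

# Precompute everything about the seed that is sphere-independent:
# per-fold seed bases, reduced train/test seed data, filtered means for FC.
searchlight_seed_context <- function(seed_rs, cfg) {
  m <- seed_rs$m
  ctx <- list(seed_rs = seed_rs, m = m)
  if (cfg$metric %in% c("mvpd_rbar", "mvpd_v", "mvpd_rbar_per_dim")) {
    folds <- lapply(seq_len(m), function(i) {
      y_train <- rs_concat(seed_rs, exclude = i)
      by <- fit_pca(y_train, k_max_ceiling = cfg$k_max)
      k <- if (cfg$component_mode == "bic") select_k_bic(by)
           else min(cfg$k_fixed, by$k_max)
      by <- set_k(by, k)
      list(basis = by,
           y_train_red = project(y_train, by)$values,
           y_test_red = project(seed_rs$runs[[i]]$values, by)$values,
           y_test_vox = seed_rs$runs[[i]]$values,
           weights = dependence_weights(by, k, cfg$weights))
    })
    ctx$folds <- folds
    ctx$k_y <- min(vapply(folds, function(f) f$basis$k, integer(1)))
  } else if (cfg$metric == "fc") {
    ctx$k_y <- 1L
  } else {
    ctx$k_y <- 1L
  }
  ctx
}

# Metric for one sphere, given per-run sphere matrices
searchlight_metric <- function(sphere_mats, ctx, cfg, tr_s) {
  if (cfg$remove_univariate && ncol(sphere_mats[[1]]) >= 2L)
    sphere_mats <- lapply(sphere_mats, function(mmat) mmat - rowMeans(mmat))
  if (cfg$metric == "fc") {
    sph_rs <- rs_from_matrices(sphere_mats, tr_s)
    return(suppressWarnings(
      standard_fc(ctx$seed_rs, sph_rs, cutoff_hz = cfg$fc_cutoff_hz)$r))
  }
  if (cfg$metric == "loo_univariate") {
    sph_rs <- rs_from_matrices(sphere_mats, tr_s)
    return(suppressWarnings(loo_univariate(ctx$seed_rs, sph_rs)$r_bar))
  }
  m <- ctx$m
  k_y <- ctx$k_y
  r_bar <- numeric(m)
  v_bar <- numeric(m)
  r_dims <- matrix(0, m, k_y)
  for (i in seq_len(m)) {
    f <- ctx$folds[[i]]
    x_train <- do.call(rbind, sphere_mats[-i])
    x_test <- sphere_mats[[i]]
    bx <- fit_pca(x_train, k_max_ceiling = cfg$k_max)
    kx <- if (cfg$component_mode == "bic") select_k_bic(bx)
          else min(cfg$k_fixed, bx$k_max)
    bx <- set_k(bx, kx)
    if (cfg$swap_roles) {
      # seed predicts the sphere: dependence summarized over sphere dims
      map <- fit_linear_map(f$y_train_red, project(x_train, bx)$values)
      pred <- f$y_test_red %*% map$coefficients
      r <- suppressWarnings(dimension_correlations(pred, project(x_test, bx)$values))
      w <- dependence_weights(bx, kx, cfg$weights)
      r_bar[i] <- sum(w * r)
      v_bar[i] <- voxelwise_r2(back_project(pred, bx, kx), x_test)$v_bar
      r_dims[i, ] <- r_bar[i]
    } else {
      map <- fit_linear_map(project(x_train, bx)$values, f$y_train_red)
      pred <- project(x_test, bx)$values %*% map$coefficients
      r <- suppressWarnings(dimension_correlations(pred, f$y_test_red))
      r_bar[i] <- sum(f$weights * r)
      if (cfg$metric == "mvpd_v")
        v_bar[i] <- voxelwise_r2(back_project(pred, f$basis, f$basis$k),
                                 f$y_test_vox)$v_bar
      r_dims[i, ] <- r[seq_len(k_y)]
    }
  }
  switch(cfg$metric,
         mvpd_rbar = mean(r_bar),
         mvpd_v = mean(v_bar),
         mvpd_rbar_per_dim = colMeans(r_dims))
}

#' Average a subset of per-dimension maps
#'
#' Element-wise mean of selected dimension maps (e.g. dimensions 2 and 3
#' combined into one map for contrast with dimension 1).
#'
#' @param maps List of [brain_map()]s sharing a mask (one per dimension).
#' @param dims Integer subset of `seq_along(maps)` to average.
#' @return A [brain_map()].
#' @export
average_dimension_maps <- function(maps, dims = seq_along(maps)) {
  stopifnot(length(maps) >= 1L,
            all(vapply(maps, inherits, logical(1), "brain_map")))
  dims <- as.integer(dims)
  if (any(dims < 1L) || any(dims > length(maps)))
    stop("`dims` out of range", call. = FALSE)
  vals <- rowMeans(do.call(cbind, lapply(maps[dims], `[[`, "values")))
  brain_map(maps[[1]]$mask, vals,
            label = paste0("mean_dims_", paste(dims, collapse = "_")))
}

#' Top-N voxels of a statistic map
#'
#' The mask of the `n` largest-valued voxels (NaN excluded; ties broken by
#' the canonical mask order, deterministically).
#'
#' @param map A [brain_map()].
#' @param n Number of voxels; at most the non-NaN count.
#' @return A [voxel_mask()].
#' @export
top_voxels <- function(map, n) {
  stopifnot(inherits(map, "brain_map"))
  ok <- which(is.finite(map$values))
  n <- as.integer(n)
  if (n < 1L || n > length(ok))
    stop("`n` exceeds the number of finite map voxels", call. = FALSE)
  # order() is stable: among ties, earlier canonical indices win
  sel <- ok[order(-map$values[ok])][seq_len(n)]
  voxel_mask(map$mask$grid, map$mask$voxel_indices[sel, , drop = FALSE])
}

#' Similarity matrix between statistic maps
#'
#' Pearson correlation between vectorized maps over the jointly finite
#' voxels; symmetric with unit diagonal.
#'
#' @param maps List of >= 2 [brain_map()]s sharing a mask.
#' @return Square correlation matrix with map labels as dimnames.
#' @export
map_similarity <- function(maps) {
  stopifnot(is.list(maps), length(maps) >= 2L,
            all(vapply(maps, inherits, logical(1), "brain_map")))
  sizes <- vapply(maps, function(m) length(m$values), integer(1))
  if (length(unique(sizes)) != 1L)
    stop("maps must share a mask", call. = FALSE)
  M <- do.call(cbind, lapply(maps, `[[`, "values"))
  joint <- rowSums(!is.finite(M)) == 0
  if (sum(joint) < 2L)
    stop("fewer than 2 jointly finite voxels", call. = FALSE)
  R <- stats::cor(M[joint, , drop = FALSE])
  labs <- vapply(maps, `[[`, character(1), "label")
  dimnames(R) <- list(labs, labs)
  R
}
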