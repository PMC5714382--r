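test_that("fit_linear_map solves small regressions exactly", {
  m1 <- fit_linear_map(cbind(c(1, 2, 3)), cbind(c(2, 4, 6)))
  expect_equal(m1$coefficients, matrix(2), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(m1$train_residual_ss, 0, tolerance = 1e-20, ignore_attr = TRUE)
  X <- rbind(c(1, 0), c(0, 1), c(1, 1))
  m2 <- fit_linear_map(X, X %*% c(1, -1))
  expect_equal(m2$coefficients, cbind(c(1, -1)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("fit_linear_map matches an independent pseudoinverse oracle", {
  skip_if_not_installed("MASS")
  set.seed(41)
  for (i in 1:25) {
    Tn <- sample(10:40, 1)
    kx <- sample(1:6, 1); ky <- sample(1:5, 1)
    X <- matrix(rnorm(Tn * kx), Tn, kx)
    if (i %% 3 == 0 && kx > 1) X[, kx] <- X[, 1]   # duplicated columns
    Y <- matrix(rnorm(Tn * ky), Tn, ky)
    B <- fit_linear_map(X, Y)$coefficients
    expect_lt(norm(B - oracle_lstsq(X, Y), "F"), 1e-8)
    # residuals orthogonal to the design
    expect_lt(max(abs(crossprod(X, Y - X %*% B))), 1e-8)
  }
})

test_that("prediction applies the map and back-projects through the seed basis", {
  set.seed(42)
  X <- matrix(rnorm(30 * 3), 30, 3)
  map_id <- structure(list(coefficients = diag(3),
                           train_residual_ss = rep(0, 3), fold_id = "f"),
                      class = "mvpd_linear_map")
  expect_equal(predict_timecourse(map_id, X)$reduced_prediction, X)
  map_0 <- map_id; map_0$coefficients <- matrix(0, 3, 3)
  expect_equal(max(abs(predict_timecourse(map_0, X)$reduced_prediction)), 0)
  # exact mapping with full-rank seed basis reproduces the target voxelwise
  Ydata <- matrix(rnorm(40 * 5), 40, 5)
  by <- fit_pca(Ydata)             # k_max = 5 = n
  Yred <- project(Ydata, by, k = 5)$values
  Xred <- Yred %*% diag(c(2, -1, 0.5, 1, 3))   # invertible relation
  map <- fit_linear_map(Xred, Yred)
  bundle <- predict_timecourse(map, Xred, y_basis = set_k(by, 5), k_y = 5)
  expect_equal(bundle$voxel_prediction, Ydata, tolerance = 1e-8)
})

test_that("dimension correlations handle perfect, inverted, orthogonal and constant cases", {
  set.seed(43)
  Y <- matrix(rnorm(200 * 3), 200, 3)
  expect_equal(dimension_correlations(Y, Y), rep(1, 3))
  expect_equal(dimension_correlations(-Y, Y), rep(-1, 3))
  # Gram-Schmidt: predictions orthogonal to observations
  P <- vapply(1:3, function(j) orthogonalize(rnorm(200), Y[, j]), numeric(200))
  expect_lt(max(abs(dimension_correlations(P, Y))), 1e-10)
  expect_warning(r0 <- dimension_correlations(cbind(rep(1, 200)), Y[, 1, drop = FALSE]),
                 "constant")
  expect_equal(r0, 0)
  expect_error(dimension_correlations(Y[1:2, ], Y[1:2, ]), "at least 3")
})

test_that("weighted dependence follows the singular-value weighting formula", {
  mk_basis <- function(d) structure(
    list(loadings = diag(length(d)), singular_values = d,
         train_mean = rep(0, length(d)), k = length(d), k_max = length(d),
         n_voxels = length(d), n_train_timepoints = 10, centered = TRUE),
    class = "pca_basis")
  expect_equal(weighted_dependence(c(1, 0), mk_basis(c(3, 1))), 0.75)
  expect_equal(weighted_dependence(c(0.4, 0.8), mk_basis(c(1, 1))), 0.6)
  expect_equal(weighted_dependence(0.37, mk_basis(5), k = 1), 0.37)
  # variance mode squares the spectrum
  expect_equal(weighted_dependence(c(1, 0), mk_basis(c(3, 1)), mode = "variance"),
               0.9)
  expect_error(weighted_dependence(c(1, 0), mk_basis(c(0, 0))), "zero")
})

test_that("voxelwise variance explained matches its defining arithmetic", {
  set.seed(44)
  Y <- matrix(rnorm(50 * 4), 50, 4)
  expect_equal(voxelwise_r2(Y, Y)$v_per_voxel, rep(1, 4), ignore_attr = TRUE)
  expect_equal(voxelwise_r2(matrix(0, 50, 4), Y)$v_per_voxel, rep(0, 4),
               ignore_attr = TRUE)
  expect_equal(voxelwise_r2(-Y, Y)$v_per_voxel, rep(-3, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  Yz <- Y; Yz[, 2] <- 0
  expect_warning(vr <- voxelwise_r2(Y, Yz), "zero-variance")
  expect_equal(vr$v_per_voxel[2], 0)
})

test_that("cross-validated MVPD recovers exact coupling and stays null under independence", {
  # noise-free exact latent linear coupling
  ds <- generate_synthetic_dataset(quick_spec(rng_seed = 5, noise_sd = 0))
  res <- crossvalidated_mvpd(ds$seed, ds$predictor,
                             mvpd_config(component_mode = "fixed", k_fixed = 3))
  expect_gte(res$r_bar, 0.999)
  expect_gte(res$v_bar, 0.999)
  # weights sum to 1 per fold; r_bar_i is a convex combination of r_j
  for (f in res$folds) {
    expect_equal(sum(f$weights), 1, tolerance = 1e-10)
    expect_true(all(f$weights >= 0))
    expect_gte(f$r_bar, min(f$r_per_dim) - 1e-12)
    expect_lte(f$r_bar, max(f$r_per_dim) + 1e-12)
  }
  # statistically independent regions: r_bar near zero
  set.seed(46)
  null_rbar <- vapply(1:20, function(i) {
    a <- generate_synthetic_dataset(quick_spec(rng_seed = 1000 + i,
                                               timepoints_per_run = 200,
                                               n_runs = 5))
    b <- generate_synthetic_dataset(quick_spec(rng_seed = 5000 + i,
                                               timepoints_per_run = 200,
                                               n_runs = 5))
    crossvalidated_mvpd(a$seed, b$predictor,
                        mvpd_config(component_mode = "fixed", k_fixed = 3))$r_bar
  }, numeric(1))
  expect_gte(mean(abs(null_rbar) <= 0.1), 0.95)
  # misaligned inputs rejected
  short <- ds$predictor
  short$runs[[1]] <- timecourse_matrix(short$runs[[1]]$values[1:50, ], tr_s = 2)
  expect_error(crossvalidated_mvpd(ds$seed, short), "misaligned")
})

test_that("fitted maps converge to the planted coupling as noise shrinks", {
  errs <- vapply(c(0.5, 0.1, 0.02), function(sd) {
    ds <- generate_synthetic_dataset(quick_spec(rng_seed = 9, noise_sd = sd,
                                                timepoints_per_run = 150))
    res <- crossvalidated_mvpd(ds$seed, ds$predictor,
                               mvpd_config(component_mode = "fixed", k_fixed = 3))
    1 - res$r_bar
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.01)
})

test_that("rank-1 MVPD on homogeneous regions equals leave-one-out univariate dependence", {
  # every voxel identical to the region mean: the first PC is the uniform
  # direction, so 1-dimensional MVPD and mean-based LOO dependence coincide
  set.seed(47)
  mk_homog <- function() {
    runs <- lapply(1:3, function(i) {
      base <- rnorm(90)
      timecourse_matrix(matrix(base, 90, 8), tr_s = 2, run_id = paste0("run", i))
    })
    run_set(runs)
  }
  seed_rs <- mk_homog(); pred_rs <- mk_homog()
  mv <- crossvalidated_mvpd(seed_rs, pred_rs,
                            mvpd_config(component_mode = "fixed", k_fixed = 1))
  lu <- loo_univariate(seed_rs, pred_rs)
  expect_equal(mv$r_bar_per_fold, lu$r_bar_per_fold, tolerance = 1e-8)
})
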