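test_that("searchlight localizes a planted coupled region at the map maximum", {
  px <- make_planted_volume()
  vols <- lapply(px$files$run_paths, function(f) as.array(RNifti::readNifti(f)))
  cfg <- searchlight_config(radius_mm = 2, metric = "mvpd_rbar",
                            component_mode = "fixed", k_fixed = 2)
  # external seed: the ground-truth seed region timecourses; the seed's own
  # block is excluded from the analysis mask so no sphere self-predicts
  gm_all <- px$files$masks$gm
  seed_lin <- mvpdR:::mask_linear_index(px$files$masks$seed)
  keep <- !(mvpdR:::mask_linear_index(gm_all) %in% seed_lin)
  gm <- voxel_mask(px$grid, gm_all$voxel_indices[keep, , drop = FALSE])
  map <- run_searchlight(vols, gm, px$ds$seed, cfg, tr_s = 2)
  expect_s3_class(map, "brain_map")
  expect_no_nan(map$values)
  peak <- map$mask$voxel_indices[which.max(map$values), ]
  planted <- px$files$masks$predictor$voxel_indices
  # peak lies inside the planted block
  expect_true(any(colSums(abs(t(planted) - as.integer(peak))) == 0))
  # and planted-region values dominate background
  lin <- mvpdR:::mask_linear_index(map$mask)
  inside <- lin %in% mvpdR:::mask_linear_index(px$files$masks$predictor)
  expect_gt(mean(map$values[inside]), mean(map$values[!inside]) + 0.2)
})

test_that("searchlight output is deterministic and order-independent", {
  px <- make_small_volume(62)
  vols <- lapply(px$files$run_paths, function(f) as.array(RNifti::readNifti(f)))
  cfg <- searchlight_config(radius_mm = 2, metric = "mvpd_rbar",
                            component_mode = "fixed", k_fixed = 2)
  m1 <- run_searchlight(vols, px$files$masks$gm, px$ds$seed, cfg, tr_s = 2)
  m2 <- run_searchlight(vols, px$files$masks$gm, px$ds$seed, cfg, tr_s = 2)
  expect_identical(m1$values, m2$values)
})

test_that("interior map values are invariant to enlarging the bounding volume", {
  px <- make_small_volume(63)
  vols <- lapply(px$files$run_paths, function(f) as.array(RNifti::readNifti(f)))
  cfg <- searchlight_config(radius_mm = 2, metric = "mvpd_rbar",
                            component_mode = "fixed", k_fixed = 2)
  small <- run_searchlight(vols, px$files$masks$gm, px$ds$seed, cfg, tr_s = 2)
  # pad each run into a larger grid at offset (2, 1, 1); gm mask unchanged
  off <- c(2L, 1L, 1L)
  big_grid <- voxel_grid(c(10, 9, 5))
  big_vols <- lapply(vols, function(v) {
    out <- array(0, c(big_grid$dims, dim(v)[4]))
    out[off[1] + 1:6, off[2] + 1:6, off[3] + 1:2, ] <- v
    out
  })
  big_gm <- voxel_mask(big_grid,
                       sweep(px$files$masks$gm$voxel_indices, 2L, off, "+"))
  big <- run_searchlight(big_vols, big_gm, px$ds$seed, cfg, tr_s = 2)
  expect_equal(big$values, small$values, tolerance = 1e-12)
})

test_that("FC searchlight on mean-removed data is identically zero", {
  px <- make_small_volume(64)
  vols <- lapply(px$files$run_paths, function(f) as.array(RNifti::readNifti(f)))
  cfg <- searchlight_config(radius_mm = 2, metric = "fc",
                            remove_univariate = TRUE)
  map <- run_searchlight(vols, px$files$masks$gm, px$ds$seed, cfg, tr_s = 2)
  # seed mean removed exactly -> correlation defined as 0 everywhere the
  # sphere has >= 2 voxels (all spheres at radius 2 on a full-grid mask)
  expect_true(all(abs(map$values) <= 1e-10))
})

test_that("per-dimension maps are produced per seed dimension and average elementwise", {
  px <- make_small_volume(65)
  vols <- lapply(px$files$run_paths, function(f) as.array(RNifti::readNifti(f)))
  cfg <- searchlight_config(radius_mm = 2, metric = "mvpd_rbar_per_dim",
                            component_mode = "fixed", k_fixed = 2)
  maps <- run_searchlight(vols, px$files$masks$gm, px$ds$seed, cfg, tr_s = 2)
  expect_length(maps, 2L)
  avg <- average_dimension_maps(maps, 1:2)
  expect_equal(avg$values, (maps[[1]]$values + maps[[2]]$values) / 2)
  expect_equal(average_dimension_maps(maps, 1)$values, maps[[1]]$values)
  expect_error(average_dimension_maps(maps, 3), "out of range")
  # BIC mode is rejected for per-dimension maps
  expect_error(searchlight_config(metric = "mvpd_rbar_per_dim",
                                  component_mode = "bic"), "fixed")
})

test_that("top_voxels selects the largest values with deterministic ties", {
  g <- voxel_grid(c(5, 2, 1))
  m <- voxel_mask(g, as.matrix(expand.grid(0:4, 0:1, 0)))
  vals <- c(5, 1, 4, 2, 3, NaN, 0, 0, 0, 9)
  bm <- brain_map(m, vals)
  top3 <- top_voxels(bm, 3)
  picked <- mvpdR:::mask_linear_index(top3)
  expect_setequal(picked, mvpdR:::mask_linear_index(m)[c(10, 1, 3)])
  # all-equal values: canonical order breaks ties
  flat <- brain_map(m, rep(1, 10))
  t2 <- top_voxels(flat, 2)
  expect_equal(mvpdR:::mask_linear_index(t2),
               mvpdR:::mask_linear_index(m)[1:2])
  expect_equal(length(top_voxels(bm, 9)), 9L)   # whole non-NaN mask
  expect_error(top_voxels(bm, 10), "finite")
})

test_that("map similarity is a correlation matrix over jointly finite voxels", {
  g <- voxel_grid(c(10, 10, 10))
  m <- voxel_mask(g, as.matrix(expand.grid(0:9, 0:9, 0)))
  set.seed(66)
  a <- rnorm(100)
  b <- orthogonalize(rnorm(100), a)
  maps <- list(brain_map(m, a, "a"), brain_map(m, a, "a2"),
               brain_map(m, -a, "neg"), brain_map(m, b, "orth"))
  S <- map_similarity(maps)
  expect_equal(diag(S), rep(1, 4), ignore_attr = TRUE)
  expect_equal(S, t(S))
  expect_equal(S["a", "a2"], 1)
  expect_equal(S["a", "neg"], -1)
  expect_lt(abs(S["a", "orth"]), 1e-10)
  # NaN voxels are excluded pairwise-jointly
  a_nan <- a; a_nan[1:5] <- NaN
  S2 <- map_similarity(list(brain_map(m, a_nan, "a"), brain_map(m, a, "b")))
  expect_equal(S2[1, 2], 1, tolerance = 1e-12)
  expect_error(map_similarity(list(brain_map(m, a, "a"))), "2")
})
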