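test_that("high-pass filtering removes drift and preserves fast signal", {
  tr <- 2; Tn <- 512
  t_s <- (0:(Tn - 1)) * tr
  const <- timecourse_matrix(matrix(5, Tn, 1), tr_s = tr)
  expect_equal(max(abs(highpass_filter(const, 128)$values)), 0, tolerance = 1e-10)
  # 32 s sinusoid is well above the 128 s cutoff: energy preserved.
  # Oracle: explicit projection onto the DCT drift basis.
  y <- sin(2 * pi * t_s / 32)
  filt <- highpass_filter(timecourse_matrix(cbind(y), tr_s = tr), 128)$values[, 1]
  X <- mvpdR:::dct_drift_basis(Tn, tr, 128)
  proj <- X %*% solve(crossprod(X), crossprod(X, y))
  oracle <- y - proj
  expect_equal(filt, oracle, tolerance = 1e-10, ignore_attr = TRUE)
  expect_gte(sum(filt^2), 0.99 * sum(y^2))
  # residual is orthogonal to the drift basis (coefficients all ~0)
  coefs <- solve(crossprod(X), crossprod(X, filt))
  expect_lt(max(abs(coefs)), 1e-10)
  # idempotence
  tw <- highpass_filter(highpass_filter(timecourse_matrix(cbind(y), tr_s = tr), 128), 128)
  expect_equal(tw$values[, 1], filt, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(highpass_filter(const, 3), "twice the repetition time")
})

test_that("low-pass filtering is DC-neutral and attenuates above cutoff", {
  # constant passes
  const <- timecourse_matrix(matrix(7.5, 128, 1), tr_s = 1)
  expect_equal(lowpass_filter(const, 0.1)$values[, 1], rep(7.5, 128),
               tolerance = 1e-8, ignore_attr = TRUE)
  # cutoff at/above Nyquist rejected (TR 2 s -> Nyquist 0.25 Hz)
  ts2 <- timecourse_matrix(matrix(rnorm(64), 64, 1), tr_s = 2)
  expect_error(lowpass_filter(ts2, 0.25), "Nyquist")
  # 0.2 Hz sinusoid at TR 1 s, cutoff 0.1 Hz: strongly attenuated.
  # Oracle: FFT amplitude at the stimulus frequency after filtering.
  Tn <- 1024
  y <- sin(2 * pi * 0.2 * (0:(Tn - 1)))
  out <- lowpass_filter(timecourse_matrix(cbind(y), tr_s = 1), 0.1)$values[, 1]
  expect_lte(sqrt(mean(out^2)), 0.05 * sqrt(mean(y^2)))
  bin <- round(0.2 * Tn) + 1L
  amp_ratio <- Mod(stats::fft(out))[bin] / Mod(stats::fft(y))[bin]
  expect_lt(amp_ratio, 0.01)
})

test_that("CompCor components span the latent noise subspace", {
  set.seed(21)
  Tn <- 120
  # two orthogonal latent timecourses mixed over 50 voxels, no noise
  L <- qr.Q(qr(matrix(rnorm(Tn * 2), Tn, 2)))
  W <- matrix(rnorm(2 * 50), 2, 50)
  ctrl <- timecourse_matrix(L %*% W, tr_s = 2)
  cc <- compcor_components(ctrl, 2)
  # largest principal angle between spans ~ 0
  Lc <- qr.Q(qr(sweep(L, 2, colMeans(L))))
  Qc <- qr.Q(qr(cc$regressors))
  angles <- acos(pmin(svd(crossprod(Lc, Qc))$d, 1))
  expect_lt(max(angles), 1e-6)
  # unit-norm, mutually orthogonal components
  G <- crossprod(cc$regressors)
  expect_equal(G, diag(2), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(formals(compcor_components)$n_components, 5)
  expect_error(compcor_components(timecourse_matrix(matrix(3, 50, 4), tr_s = 2), 2),
               "no variance")
  expect_error(compcor_components(ctrl, 1000), "n_components")
})

test_that("nuisance regression is an orthogonal projection", {
  set.seed(22)
  Tn <- 80
  nuis <- nuisance_set(matrix(rnorm(Tn * 3), Tn, 3), run_id = "r1")
  ts <- timecourse_matrix(cbind(nuis$regressors[, 1],
                                matrix(rnorm(Tn * 4), Tn, 4)), tr_s = 2)
  res <- regress_out(ts, nuis)
  # a column equal to a nuisance regressor is annihilated
  expect_lt(max(abs(res$values[, 1])), 1e-10)
  # residuals orthogonal to every nuisance column and the intercept
  expect_lt(max(abs(crossprod(nuis$regressors, res$values))), 1e-8)
  expect_lt(max(abs(colSums(res$values))), 1e-8)
  # idempotence (projection property)
  expect_equal(regress_out(res, nuis)$values, res$values, tolerance = 1e-10)
  # empty nuisance set = column demeaning
  empty <- nuisance_set(matrix(0, Tn, 0))
  expect_equal(regress_out(ts, empty)$values,
               sweep(ts$values, 2, colMeans(ts$values)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # rank-deficient set warns but still projects
  dup <- nuisance_set(cbind(nuis$regressors, nuis$regressors[, 1]))
  expect_warning(res2 <- regress_out(ts, dup), "rank-deficient")
  expect_equal(res2$values, res$values, tolerance = 1e-8)
})

test_that("high-pass output is unchanged by regressing the drift basis", {
  set.seed(23)
  ts <- timecourse_matrix(matrix(rnorm(256 * 3), 256, 3), tr_s = 2)
  hp <- highpass_filter(ts, 128)
  drift <- nuisance_set(mvpdR:::dct_drift_basis(256, 2, 128))
  expect_equal(suppressWarnings(regress_out(hp, drift)$values), hp$values,
               tolerance = 1e-8)
})

test_that("censoring drops flagged rows and enforces minimum length", {
  ts <- timecourse_matrix(matrix(1:10, 5, 2), tr_s = 2)
  expect_equal(apply_censor(ts, censor_vector(rep(TRUE, 5)))$values, ts$values)
  kept <- apply_censor(ts, censor_vector(c(TRUE, TRUE, TRUE, FALSE, FALSE)))
  expect_equal(kept$values, ts$values[1:3, ])
  expect_error(censor_vector(rep(FALSE, 5)), "at least 2")
  expect_error(apply_censor(ts, censor_vector(c(TRUE, TRUE))), "length")
})

test_that("univariate-signal removal zeroes spatial means and is idempotent", {
  r <- remove_univariate_signal(timecourse_matrix(rbind(c(1, 2, 3), c(4, 5, 6)),
                                                  tr_s = 2))
  expect_equal(r$values[1, ], c(-1, 0, 1), ignore_attr = TRUE)
  set.seed(24)
  ts <- timecourse_matrix(matrix(rnorm(60 * 7), 60, 7), tr_s = 2)
  out <- remove_univariate_signal(ts)
  expect_lt(max(abs(rowSums(out$values))), 1e-12)
  expect_equal(remove_univariate_signal(out)$values, out$values,
               tolerance = 1e-12)
  expect_error(remove_univariate_signal(timecourse_matrix(matrix(1:5, 5, 1),
                                                          tr_s = 2)),
               "at least 2 voxels")
})
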