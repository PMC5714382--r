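#' Canonical double-gamma HRF kernel
#'
#' SPM-style haemodynamic response: a gamma density peaking around 5 s
#' minus a scaled undershoot gamma peaking around 15 s, sampled at the
#' repetition time. Convolving white noise with this kernel gives latent
#' timecourses with BOLD-plausible autocorrelation.
#'
#' @param tr_s Sampling interval in seconds.
#' @param duration_s Kernel support in seconds (default 32).
#' @return Numeric kernel (unit sum of absolute values).
#' @export
canonical_hrf <- function(tr_s = 2, duration_s = 32) {
  t <- seq(0, duration_s, by = tr_s)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / sum(abs(h))
}

# white noise convolved with the HRF, standardized per column
smooth_latents <- function(n_timepoints, k, tr_s) {
  h <- canonical_hrf(tr_s)
  raw <- matrix(stats::rnorm((n_timepoints + length(h)) * k, 0, 1),
                n_timepoints + length(h), k)
  sm <- apply(raw, 2L, function(col)
    stats::convolve(col, rev(h), type = "open")[seq_len(n_timepoints + length(h))])
  sm <- sm[-seq_len(length(h)), , drop = FALSE]   # drop warm-up edge
  sm <- scale(sm)
  attr(sm, "scaled:center") <- NULL
  attr(sm, "scaled:scale") <- NULL
  matrix(sm, n_timepoints, k)
}

# random loading matrix with orthonormal columns; pattern_only projects
# the columns orthogonal to the uniform direction first
random_loadings <- function(n_voxels, k, pattern_only = FALSE) {
  if (pattern_only && n_voxels < k + 1L)
    stop("pattern_only needs n_voxels > n_latent", call. = FALSE)
  A <- matrix(stats::rnorm(n_voxels * k), n_voxels, k)
  if (pattern_only) A <- sweep(A, 2L, colMeans(A))
  Q <- qr.Q(qr(A))[, seq_len(k), drop = FALSE]
  if (pattern_only) {
    # re-orthonormalize within the zero-sum subspace
    Q <- sweep(Q, 2L, colMeans(Q))
    Q <- qr.Q(qr(Q))[, seq_len(k), drop = FALSE]
    Q <- sweep(Q, 2L, colMeans(Q))  # numerically re-center
  }
  Q
}

#' Specification of a synthetic multi-run dataset
#'
#' Describes a two-region (predictor and seed) multi-run dataset with known
#' low-rank latent structure: predictor latents are HRF-smoothed Gaussian
#' processes; seed latents are a fixed linear transform (`coupling`) of the
#' predictor latents plus innovation noise; each region's voxel data are
#' latents times a spatial loading matrix, plus an optional shared
#' spatial-mean (univariate) component common to both regions, plus
#' additive Gaussian noise.
#'
#' Defaults mirror a typical slow event-related design: 3 runs of 360
#' volumes at TR 2 s, 80-voxel regions with 3 latent dimensions, per-voxel
#' signal and noise standard deviations of 1.
#'
#' @param n_runs Number of runs (>= 2).
#' @param timepoints_per_run Volumes per run.
#' @param tr_s Repetition time in seconds (default 2).
#' @param regions List with elements `predictor` and `seed`, each a list
#'   with `n_voxels` and `n_latent`.
#' @param coupling Latent-to-latent matrix `B_true`
#'   (`n_latent_predictor` x `n_latent_seed`); `NULL` draws a random one
#'   (scaled to unit spectral norm) from the seed.
#' @param noise_sd Additive voxel noise SD.
#' @param innovation_sd SD of the seed-latent innovation noise (0 = exact
#'   linear coupling).
#' @param shared_mean_amplitude Amplitude of the shared spatial-mean
#'   timecourse added uniformly to every voxel of both regions (0 = no
#'   univariate component).
#' @param signal_amplitude Approximate per-voxel signal SD contributed by
#'   the latents.
#' @param pattern_only Force each signal loading column to sum to zero, so
#'   the noiseless signal has zero spatial mean at every timepoint (the
#'   scenario invisible to mean-based connectivity).
#' @param rng_seed Integer seed; the same seed reproduces the dataset
#'   bit-exactly.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_runs = 3, timepoints_per_run = 360, tr_s = 2,
                           regions = list(
                             predictor = list(n_voxels = 80, n_latent = 3),
                             seed = list(n_voxels = 80, n_latent = 3)),
                           coupling = NULL, noise_sd = 1, innovation_sd = 0,
                           shared_mean_amplitude = 0, signal_amplitude = 1,
                           pattern_only = FALSE, rng_seed = 1) {
  n_runs <- as.integer(n_runs)
  timepoints_per_run <- as.integer(timepoints_per_run)
  if (n_runs < 2L) stop("`n_runs` must be >= 2", call. = FALSE)
  if (timepoints_per_run < 3L)
    stop("`timepoints_per_run` must be >= 3", call. = FALSE)
  for (nm in c("predictor", "seed")) {
    r <- regions[[nm]]
    if (is.null(r) || r$n_voxels < 1L || r$n_latent < 1L)
      stop("each region needs positive `n_voxels` and `n_latent`",
           call. = FALSE)
    if (r$n_latent > r$n_voxels)
      stop("`n_latent` cannot exceed `n_voxels`", call. = FALSE)
  }
  if (!is.null(coupling)) {
    coupling <- as.matrix(coupling)
    if (nrow(coupling) != regions$predictor$n_latent ||
        ncol(coupling) != regions$seed$n_latent)
      stop("`coupling` must be n_latent_predictor x n_latent_seed",
           call. = FALSE)
  }
  if (noise_sd < 0 || innovation_sd < 0 || shared_mean_amplitude < 0 ||
      signal_amplitude <= 0)
    stop("amplitudes must be nonnegative (signal_amplitude positive)",
         call. = FALSE)
  structure(list(n_runs = n_runs, timepoints_per_run = timepoints_per_run,
                 tr_s = tr_s, regions = regions, coupling = coupling,
                 noise_sd = noise_sd, innovation_sd = innovation_sd,
                 shared_mean_amplitude = shared_mean_amplitude,
                 signal_amplitude = signal_amplitude,
                 pattern_only = isTRUE(pattern_only),
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic dataset with known ground truth
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `synthetic_dataset`: `predictor` and `seed`
#'   [run_set()]s plus `ground_truth` (loadings, `B_true`, latent
#'   timecourses per run, shared-mean timecourses, and the generating
#'   [synthetic_spec()]).
#' @export
generate_synthetic_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$rng_seed)
  kx <- spec$regions$predictor$n_latent
  ky <- spec$regions$seed$n_latent
  nx <- spec$regions$predictor$n_voxels
  ny <- spec$regions$seed$n_voxels

  B_true <- spec$coupling
  if (is.null(B_true)) {
    B_true <- matrix(stats::rnorm(kx * ky), kx, ky)
    B_true <- B_true / max(svd(B_true)$d)
  }
  Wx <- random_loadings(nx, kx, spec$pattern_only) *
    spec$signal_amplitude * sqrt(nx / kx)
  Wy <- random_loadings(ny, ky, spec$pattern_only) *
    spec$signal_amplitude * sqrt(ny / ky)

  Tn <- spec$timepoints_per_run
  lat_x <- list(); lat_y <- list(); shared <- list()
  x_runs <- list(); y_runs <- list()
  for (i in seq_len(spec$n_runs)) {
    Lx <- smooth_latents(Tn, kx, spec$tr_s)
    Ly <- Lx %*% B_true
    if (spec$innovation_sd > 0)
      Ly <- Ly + spec$innovation_sd * matrix(stats::rnorm(Tn * ky), Tn, ky)
    g <- if (spec$shared_mean_amplitude > 0)
      spec$shared_mean_amplitude * smooth_latents(Tn, 1, spec$tr_s)[, 1]
    else rep(0, Tn)
    Xd <- Lx %*% t(Wx) + g +
      spec$noise_sd * matrix(stats::rnorm(Tn * nx), Tn, nx)
    Yd <- Ly %*% t(Wy) + g +
      spec$noise_sd * matrix(stats::rnorm(Tn * ny), Tn, ny)
    lat_x[[i]] <- Lx; lat_y[[i]] <- Ly; shared[[i]] <- g
    x_runs[[i]] <- timecourse_matrix(Xd, tr_s = spec$tr_s,
                                     run_id = paste0("run", i))
    y_runs[[i]] <- timecourse_matrix(Yd, tr_s = spec$tr_s,
                                     run_id = paste0("run", i))
  }
  structure(list(predictor = run_set(x_runs), seed = run_set(y_runs),
                 ground_truth = list(B_true = B_true, loadings_predictor = Wx,
                                     loadings_seed = Wy,
                                     latents_predictor = lat_x,
                                     latents_seed = lat_y,
                                     shared_mean = shared, spec = spec)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  s <- x$ground_truth$spec
  cat(sprintf(paste0("<synthetic_dataset> %d runs x %d volumes, TR %.3g s; ",
                     "predictor %d voxels (%d latents) -> seed %d voxels (%d latents)\n"),
              s$n_runs, s$timepoints_per_run, s$tr_s,
              s$regions$predictor$n_voxels, s$regions$predictor$n_latent,
              s$regions$seed$n_voxels, s$regions$seed$n_latent))
  invisible(x)
}

#' Build a target/distractor trial roster
#'
#' Enumerates labeled trials across two stimulus modalities (faces and
#' voices): each of `n_distractor_identities` distractor identities appears
#' `n_per_distractor` times per modality and the target identity appears
#' `n_target` times per modality; the order is then shuffled
#' deterministically from `rng_seed`. With the default counts (target 8,
#' two distractors at 16 each, two modalities) targets make up 20% of
#' trials.
#'
#' @param n_target Target presentations per modality (default 8).
#' @param n_distractor_identities Number of distractor identities
#'   (default 2).
#' @param n_per_distractor Presentations of each distractor per modality
#'   (default 16).
#' @param rng_seed Shuffle seed.
#' @return List with `roster` (data.frame: trial, modality, identity,
#'   role) and `target_proportion`.
#' @export
make_trial_design <- function(n_target = 8, n_distractor_identities = 2,
                              n_per_distractor = 16, rng_seed = 1) {
  n_target <- as.integer(n_target)
  n_distractor_identities <- as.integer(n_distractor_identities)
  n_per_distractor <- as.integer(n_per_distractor)
  if (n_target < 1L || n_distractor_identities < 0L || n_per_distractor < 1L)
    stop("counts must be positive", call. = FALSE)
  modalities <- c("face", "voice")
  rows <- list()
  for (mod in modalities) {
    rows[[length(rows) + 1L]] <-
      data.frame(modality = mod, identity = "target", role = "target",
                 count = n_target)
    if (n_distractor_identities > 0L)
      rows[[length(rows) + 1L]] <-
        data.frame(modality = mod,
                   identity = paste0("distractor", seq_len(n_distractor_identities)),
                   role = "distractor", count = n_per_distractor)
  }
  tab <- do.call(rbind, rows)
  roster <- tab[rep(seq_len(nrow(tab)), tab$count), c("modality", "identity", "role")]
  set.seed(rng_seed)
  roster <- roster[sample.int(nrow(roster)), ]
  roster$trial <- seq_len(nrow(roster))
  rownames(roster) <- NULL
  roster <- roster[, c("trial", "modality", "identity", "role")]
  list(roster = roster,
       target_proportion = mean(roster$role == "target"))
}

#' Write a synthetic dataset as NIfTI volumes and masks
#'
#' Places the predictor and seed regions as non-overlapping rectangular
#' blocks in a 3D grid, fills the remaining voxels with Gaussian noise of
#' the dataset's noise SD, and writes per-run 4D volumes plus region masks
#' and a whole-grid gray-matter mask, ready for [load_run_timecourses()]
#' and [run_searchlight()].
#'
#' @param dataset A [generate_synthetic_dataset()] output.
#' @param grid A [voxel_grid()] large enough to hold both regions.
#' @param placement Named list of 0-based block corner coordinates, e.g.
#'   `list(predictor = c(0, 0, 0), seed = c(6, 0, 0))`.
#' @param dir Output directory.
#' @return List with `run_paths`, `mask_paths` (predictor, seed, gm),
#'   `masks` (the [voxel_mask()] objects) and `grid`.
#' @export
write_as_volumes <- function(dataset, grid, placement, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"),
            inherits(grid, "voxel_grid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- dataset$ground_truth$spec
  region_names <- c("predictor", "seed")
  masks <- list()
  lins <- list()
  for (nm in region_names) {
    n <- spec$regions[[nm]]$n_voxels
    corner <- placement[[nm]]
    if (is.null(corner))
      stop("placement missing region: ", nm, call. = FALSE)
    side <- ceiling(n^(1 / 3))
    block <- as.matrix(expand.grid(x = 0:(side - 1), y = 0:(side - 1),
                                   z = 0:(side - 1)))
    block <- block[order(block[, 1], block[, 2], block[, 3]), , drop = FALSE]
    block <- sweep(block[seq_len(n), , drop = FALSE], 2L, corner, "+")
    if (any(block < 0) || any(t(block) >= grid$dims))
      stop("region block does not fit in the grid: ", nm, call. = FALSE)
    masks[[nm]] <- voxel_mask(grid, block)
    lins[[nm]] <- mask_linear_index(masks[[nm]])
  }
  if (length(intersect(lins$predictor, lins$seed)) > 0L)
    stop("region blocks overlap", call. = FALSE)

  # data columns are in canonical mask order already (blocks built sorted)
  run_paths <- character(spec$n_runs)
  set.seed(spec$rng_seed + 104729L)  # background noise stream
  for (i in seq_len(spec$n_runs)) {
    Tn <- spec$timepoints_per_run
    vol <- array(stats::rnorm(prod(grid$dims) * Tn, 0, max(spec$noise_sd, 1e-6)),
                 c(grid$dims, Tn))
    flat <- matrix(vol, prod(grid$dims), Tn)
    flat[lins$predictor, ] <- t(dataset$predictor$runs[[i]]$values)
    flat[lins$seed, ] <- t(dataset$seed$runs[[i]]$values)
    vol <- array(flat, c(grid$dims, Tn))
    img <- RNifti::asNifti(vol)
    RNifti::pixdim(img) <- c(grid$voxel_size_mm, spec$tr_s)
    run_paths[i] <- file.path(dir, sprintf("run%02d.nii.gz", i))
    RNifti::writeNifti(img, run_paths[i], datatype = "float")
  }
  gm <- voxel_mask(grid, as.matrix(expand.grid(
    x = 0:(grid$dims[1] - 1), y = 0:(grid$dims[2] - 1),
    z = 0:(grid$dims[3] - 1))))
  mask_paths <- list(
    predictor = write_mask(masks$predictor, file.path(dir, "predictor_mask.nii.gz")),
    seed = write_mask(masks$seed, file.path(dir, "seed_mask.nii.gz")),
    gm = write_mask(gm, file.path(dir, "gm_mask.nii.gz")))
  list(run_paths = run_paths, mask_paths = mask_paths,
       masks = c(masks, list(gm = gm)), grid = grid)
}
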