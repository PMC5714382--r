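#' Voxel grid geometry
#'
#' A `voxel_grid` describes the sampling geometry of a volume: the number of
#' voxels along each axis, the voxel size in millimetres, and a 4x4 affine
#' transform mapping 0-based voxel indices to world (mm) coordinates. All
#' distances used by [sphere_mask()] are computed in world millimetres through
#' this affine, so anisotropic voxels are supported; the conventional fMRI
#' case is a 2 mm isotropic grid.
#'
#' @param dims Integer vector of length 3: voxels along x, y, z.
#' @param voxel_size_mm Numeric vector of length 3, all positive.
#' @param affine Optional 4x4 affine; defaults to a diagonal scaling by
#'   `voxel_size_mm` with the origin at voxel (0, 0, 0).
#' @return An object of class `voxel_grid`.
#' @export
#' @examples
#' g <- voxel_grid(c(10, 10, 10))
#' g$voxel_size_mm
voxel_grid <- function(dims, voxel_size_mm = c(2, 2, 2), affine = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("`dims` must be 3 positive integers", call. = FALSE)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be 3 positive reals", call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine)))
      stop("`affine` must be a finite 4x4 matrix", call. = FALSE)
    if (abs(det(affine)) < .Machine$double.eps)
      stop("`affine` must be invertible", call. = FALSE)
  }
  structure(list(dims = dims, voxel_size_mm = voxel_size_mm, affine = affine),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  invisible(x)
}

#' Map 0-based voxel indices to world mm coordinates
#'
#' @param grid A [voxel_grid()].
#' @param ijk Integer matrix (rows = voxels, 3 columns) of 0-based indices.
#' @return Numeric matrix of world coordinates (mm), one row per voxel.
#' @export
voxel_to_world <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  xyz1 <- cbind(ijk, 1) %*% t(grid$affine)
  xyz1[, 1:3, drop = FALSE]
}

grids_equal <- function(a, b, tol = 1e-6) {
  all(a$dims == b$dims) &&
    max(abs(a$affine - b$affine)) <= tol
}

#' Voxel mask on a grid
#'
#' An ordered set of distinct voxel coordinates on a [voxel_grid()]. The
#' ordering is canonical (ascending lexicographic on x, then y, then z) so
#' that the column order of extracted timecourse matrices is deterministic
#' and reproducible.
#'
#' @param grid A [voxel_grid()].
#' @param voxel_indices Integer matrix (n x 3) of 0-based voxel coordinates.
#' @return An object of class `voxel_mask` with elements `grid` and
#'   `voxel_indices` (canonically ordered, duplicate-free).
#' @export
#' @examples
#' g <- voxel_grid(c(4, 4, 4))
#' m <- voxel_mask(g, rbind(c(1, 1, 1), c(0, 0, 0)))
#' m$voxel_indices  # reordered canonically
voxel_mask <- function(grid, voxel_indices) {
  stopifnot(inherits(grid, "voxel_grid"))
  vi <- matrix(as.integer(round(voxel_indices)), ncol = 3L)
  if (nrow(vi) == 0L)
    stop("mask must contain at least one voxel", call. = FALSE)
  if (any(vi < 0L) || any(t(vi) >= grid$dims))
    stop("mask voxel indices outside grid dims", call. = FALSE)
  vi <- unique(vi)
  vi <- vi[order(vi[, 1], vi[, 2], vi[, 3]), , drop = FALSE]
  structure(list(grid = grid, voxel_indices = vi), class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> %d voxels on %d x %d x %d grid\n",
              nrow(x$voxel_indices), x$grid$dims[1], x$grid$dims[2],
              x$grid$dims[3]))
  invisible(x)
}

#' @export
length.voxel_mask <- function(x) nrow(x$voxel_indices)

# 1-based linear indices into an array of dim grid$dims
mask_linear_index <- function(mask) {
  d <- mask$grid$dims
  vi <- mask$voxel_indices
  1L + vi[, 1] + d[1] * (vi[, 2] + d[2] * vi[, 3])
}

mask_contains <- function(mask, ijk) {
  d <- mask$grid$dims
  key <- 1 + ijk[1] + d[1] * (ijk[2] + d[2] * ijk[3])
  key %in% mask_linear_index(mask)
}

#' Spherical searchlight mask
#'
#' Builds the mask of voxels whose centre-to-centre Euclidean distance (in
#' world mm, through the grid affine) from `center` is at most `radius_mm`,
#' intersected with `restrict_to` (typically the gray-matter mask). The
#' centre voxel is always included. With a 6 mm radius on a 2 mm isotropic
#' grid and no truncation, the sphere contains 123 voxels.
#'
#' @param center 0-based voxel coordinate (length-3 integer), inside
#'   `restrict_to`.
#' @param radius_mm Sphere radius in millimetres (>= 0).
#' @param grid A [voxel_grid()].
#' @param restrict_to Optional [voxel_mask()] to intersect with; `NULL` means
#'   the full grid.
#' @return A [voxel_mask()].
#' @export
#' @examples
#' g <- voxel_grid(c(15, 15, 15))
#' length(sphere_mask(c(7, 7, 7), 6, g))  # 123
sphere_mask <- function(center, radius_mm, grid, restrict_to = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  center <- as.integer(round(center))
  if (length(center) != 3L || any(center < 0L) || any(center >= grid$dims))
    stop("`center` must be a 0-based voxel coordinate inside the grid",
         call. = FALSE)
  if (!is.numeric(radius_mm) || radius_mm < 0)
    stop("`radius_mm` must be nonnegative", call. = FALSE)
  if (!is.null(restrict_to)) {
    stopifnot(inherits(restrict_to, "voxel_mask"))
    if (!grids_equal(grid, restrict_to$grid))
      stop("`restrict_to` is defined on a different grid", call. = FALSE)
    if (!mask_contains(restrict_to, center))
      stop("`center` is outside `restrict_to`", call. = FALSE)
  }
  off <- sphere_offsets(radius_mm, grid)
  cand <- sweep(off, 2L, center, "+")
  keep <- cand[, 1] >= 0L & cand[, 1] < grid$dims[1] &
    cand[, 2] >= 0L & cand[, 2] < grid$dims[2] &
    cand[, 3] >= 0L & cand[, 3] < grid$dims[3]
  cand <- cand[keep, , drop = FALSE]
  if (!is.null(restrict_to)) {
    d <- grid$dims
    lin <- 1 + cand[, 1] + d[1] * (cand[, 2] + d[2] * cand[, 3])
    cand <- cand[lin %in% mask_linear_index(restrict_to), , drop = FALSE]
  }
  voxel_mask(grid, cand)
}

# integer offsets (rows) within radius_mm of the origin, in world distance
sphere_offsets <- function(radius_mm, grid) {
  # bounding box in voxel units per axis; affine may rotate, so be generous:
  # use the smallest singular value of the 3x3 linear part as the minimum
  # world displacement per unit voxel step
  A <- grid$affine[1:3, 1:3]
  smin <- min(svd(A)$d)
  r_vox <- ceiling(radius_mm / max(smin, .Machine$double.eps)) + 1L
  rng <- -r_vox:r_vox
  off <- as.matrix(expand.grid(dx = rng, dy = rng, dz = rng))
  w <- off %*% t(A)
  d2 <- rowSums(w^2)
  off[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
}

#' Gray-matter mask from tissue probability maps
#'
#' Smooths each probability map with a Gaussian kernel of the given FWHM
#' (sigma = FWHM / (2 sqrt(2 ln 2)) per axis, truncated at 4 sigma, edge
#' renormalized), averages the smoothed maps across subjects, and keeps
#' voxels whose average is at least `threshold`.
#'
#' @param probability_maps List of 3D arrays with values in `[0, 1]`, all on
#'   the grid `grid`.
#' @param grid A [voxel_grid()] describing the maps.
#' @param fwhm_mm Gaussian smoothing FWHM in millimetres (0 disables
#'   smoothing).
#' @param threshold Inclusion threshold in `[0, 1]`. There is no default:
#'   the voxel count of the resulting mask depends strongly on it.
#' @return A [voxel_mask()] of voxels with smoothed average `>= threshold`.
#' @export
build_gray_matter_mask <- function(probability_maps, grid, fwhm_mm, threshold) {
  if (!is.list(probability_maps) || length(probability_maps) == 0L)
    stop("`probability_maps` must be a nonempty list of 3D arrays",
         call. = FALSE)
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("`threshold` must be in [0, 1]", call. = FALSE)
  sm <- lapply(probability_maps, function(p) {
    p <- as.array(p)
    if (!all(dim(p) == grid$dims))
      stop("probability map dims do not match grid", call. = FALSE)
    if (any(p < -1e-9) || any(p > 1 + 1e-9))
      stop("probability map values must lie in [0, 1]", call. = FALSE)
    gaussian_smooth_3d(p, fwhm_mm, grid$voxel_size_mm)
  })
  avg <- Reduce(`+`, sm) / length(sm)
  keep <- which(avg >= threshold, arr.ind = TRUE)
  if (nrow(keep) == 0L)
    stop("gray-matter mask is empty at this threshold", call. = FALSE)
  voxel_mask(grid, keep - 1L)
}

# separable Gaussian smoothing with edge renormalization
gaussian_smooth_3d <- function(vol, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm <= 0) return(vol)
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / voxel_size_mm
  ones <- array(1, dim(vol))
  num <- vol
  den <- ones
  for (ax in 1:3) {
    k <- gauss_kernel(sigma_vox[ax])
    if (length(k) > 1L) {
      num <- convolve_axis(num, k, ax)
      den <- convolve_axis(den, k, ax)
    }
  }
  num / den
}

gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(4 * sigma))
  x <- -h:h
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 1D convolution along axis `ax` of a 3D array, zero padded
convolve_axis <- function(vol, k, ax) {
  d <- dim(vol)
  h <- (length(k) - 1L) / 2L
  perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  v <- aperm(vol, perm)
  dm <- dim(v)
  m <- matrix(v, nrow = dm[1])
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    shift <- j - 1L - h
    src <- (1:n) + shift
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + k[j] * m[src[ok], ]
  }
  v <- array(out, dm)
  aperm(v, order(perm))
}
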