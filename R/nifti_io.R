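#' Extract a region's timecourses from a 4D volume
#'
#' Reads a 4D BOLD volume (NIfTI path or in-memory array) and returns the
#' T x n matrix of timecourses for the voxels of `mask`, columns in the
#' mask's canonical order.
#'
#' @param volume Path to a 4D NIfTI file, or a 4D array.
#' @param mask A [voxel_mask()] on the volume's grid.
#' @param tr_s Repetition time in seconds.
#' @param run_id Run label.
#' @return A [timecourse_matrix()].
#' @export
load_run_timecourses <- function(volume, mask, tr_s, run_id = "run1") {
  stopifnot(inherits(mask, "voxel_mask"))
  arr <- load_volume_array(volume)
  if (length(dim(arr)) != 4L)
    stop("volume must be 4D (x, y, z, time)", call. = FALSE)
  if (!all(dim(arr)[1:3] == mask$grid$dims))
    stop("volume grid does not match mask grid", call. = FALSE)
  nt <- dim(arr)[4]
  if (nt < 2L)
    stop("volume must contain at least 2 timepoints", call. = FALSE)
  lin <- mask_linear_index(mask)
  dim(arr) <- c(prod(mask$grid$dims), nt)
  vals <- t(arr[lin, , drop = FALSE])
  timecourse_matrix(vals, tr_s = tr_s, run_id = run_id, voxel_order = mask)
}

load_volume_array <- function(volume) {
  if (is.character(volume)) {
    if (!file.exists(volume))
      stop("volume file not found: ", volume, call. = FALSE)
    volume <- RNifti::readNifti(volume)
  }
  arr <- as.array(volume)
  storage.mode(arr) <- "double"
  arr
}

#' Per-voxel statistic map over a mask
#'
#' @param mask A [voxel_mask()] (typically the gray-matter mask).
#' @param values One value per mask voxel (NA/NaN marks skipped voxels).
#' @param label Map label, used in manifests and file names.
#' @return An object of class `brain_map`.
#' @export
brain_map <- function(mask, values, label = "map") {
  stopifnot(inherits(mask, "voxel_mask"))
  values <- as.numeric(values)
  if (length(values) != length(mask))
    stop("need exactly one value per mask voxel", call. = FALSE)
  structure(list(mask = mask, values = values, label = as.character(label)),
            class = "brain_map")
}

#' @export
print.brain_map <- function(x, ...) {
  ok <- is.finite(x$values)
  cat(sprintf("<brain_map> '%s': %d voxels (%d finite), range [%.4g, %.4g]\n",
              x$label, length(x$values), sum(ok),
              if (any(ok)) min(x$values[ok]) else NA,
              if (any(ok)) max(x$values[ok]) else NA))
  invisible(x)
}

#' Write a statistic map as a 3D NIfTI volume
#'
#' Mask voxels carry the statistic; background voxels are NaN, so "not
#' computed" is distinguishable from a true zero. Values round-trip at
#' 32-bit float precision.
#'
#' @param map A [brain_map()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_brain_map <- function(map, path) {
  stopifnot(inherits(map, "brain_map"))
  if (length(map$values) == 0L)
    stop("empty map", call. = FALSE)
  g <- map$mask$grid
  arr <- array(NaN, g$dims)
  arr[mask_linear_index(map$mask)] <- map$values
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- g$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a statistic map written by [write_brain_map()]
#'
#' @param path NIfTI path.
#' @param mask Optional [voxel_mask()]; by default the mask is recovered as
#'   the non-NaN voxels of the volume.
#' @param label Map label.
#' @return A [brain_map()].
#' @export
read_brain_map <- function(path, mask = NULL, label = "map") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D statistic volume", call. = FALSE)
  if (is.null(mask)) {
    vs <- RNifti::pixdim(img)[1:3]
    grid <- voxel_grid(dim(arr), vs)
    keep <- which(!is.nan(arr), arr.ind = TRUE)
    if (nrow(keep) == 0L) stop("map volume is all NaN", call. = FALSE)
    mask <- voxel_mask(grid, keep - 1L)
  } else {
    if (!all(dim(arr) == mask$grid$dims))
      stop("volume grid does not match mask grid", call. = FALSE)
  }
  brain_map(mask, arr[mask_linear_index(mask)], label = label)
}

#' Write a mask as a binary NIfTI volume
#'
#' @param mask A [voxel_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  g <- mask$grid
  arr <- array(0L, g$dims)
  arr[mask_linear_index(mask)] <- 1L
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- g$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a binary mask volume
#'
#' @param path NIfTI path.
#' @param grid Optional [voxel_grid()]; defaults to the file's geometry.
#' @return A [voxel_mask()] of the nonzero voxels.
#' @export
read_mask <- function(path, grid = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D mask volume", call. = FALSE)
  if (is.null(grid)) grid <- voxel_grid(dim(arr), RNifti::pixdim(img)[1:3])
  keep <- which(arr != 0, arr.ind = TRUE)
  if (nrow(keep) == 0L) stop("mask volume is empty", call. = FALSE)
  voxel_mask(grid, keep - 1L)
}

#' Read/write masks as TSV voxel-index lists
#'
#' Grid-free text interchange: three integer columns `x`, `y`, `z` of
#' 0-based voxel indices.
#'
#' @param mask A [voxel_mask()].
#' @param path TSV path.
#' @return `write_mask_tsv()`: `path` invisibly; `read_mask_tsv()`: a
#'   [voxel_mask()].
#' @export
write_mask_tsv <- function(mask, path) {
  df <- as.data.frame(mask$voxel_indices)
  names(df) <- c("x", "y", "z")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mask_tsv
#' @param grid A [voxel_grid()] the indices refer to.
#' @export
read_mask_tsv <- function(path, grid) {
  df <- utils::read.delim(path)
  voxel_mask(grid, as.matrix(df[, c("x", "y", "z")]))
}
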