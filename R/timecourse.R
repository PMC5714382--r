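#' Timecourse matrix for one run
#'
#' Container for one run's responses in one region: a T x n matrix with
#' timepoints as rows and voxels as columns, plus the repetition time and a
#' run label. Column order follows the canonical ordering of the mask that
#' defined the region (when one is attached).
#'
#' @param values Numeric T x n matrix (timepoints x voxels), finite, T >= 2.
#' @param tr_s Repetition time in seconds.
#' @param run_id Run label.
#' @param voxel_order Optional [voxel_mask()] that defined the columns.
#' @return An object of class `timecourse_matrix`.
#' @export
timecourse_matrix <- function(values, tr_s, run_id = "run1",
                              voxel_order = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L)
    stop("a timecourse needs at least 2 timepoints", call. = FALSE)
  if (ncol(values) < 1L)
    stop("a timecourse needs at least 1 voxel", call. = FALSE)
  if (!all(is.finite(values)))
    stop("timecourse values must be finite", call. = FALSE)
  if (!is.numeric(tr_s) || tr_s <= 0)
    stop("`tr_s` must be a positive repetition time in seconds",
         call. = FALSE)
  if (!is.null(voxel_order)) {
    stopifnot(inherits(voxel_order, "voxel_mask"))
    if (length(voxel_order) != ncol(values))
      stop("column count does not match `voxel_order`", call. = FALSE)
  }
  structure(list(values = values, tr_s = tr_s, run_id = as.character(run_id),
                 voxel_order = voxel_order),
            class = "timecourse_matrix")
}

#' @export
print.timecourse_matrix <- function(x, ...) {
  cat(sprintf("<timecourse_matrix> run '%s': %d timepoints x %d voxels, TR %.3g s\n",
              x$run_id, nrow(x$values), ncol(x$values), x$tr_s))
  invisible(x)
}

#' @export
dim.timecourse_matrix <- function(x) dim(x$values)

#' Multi-run set of timecourse matrices
#'
#' Cross-validation operates on a `run_set`: two or more runs from the same
#' region, sharing voxel count, column order and repetition time.
#'
#' @param runs List of [timecourse_matrix()] objects (>= 2, for
#'   leave-one-run-out cross-validation).
#' @return An object of class `run_set` with elements `runs` and `m`.
#' @export
run_set <- function(runs) {
  if (!is.list(runs) || length(runs) < 2L)
    stop("a run_set needs at least 2 runs (leave-one-run-out requires it)",
         call. = FALSE)
  if (!all(vapply(runs, inherits, logical(1), "timecourse_matrix")))
    stop("all elements must be timecourse_matrix objects", call. = FALSE)
  n <- vapply(runs, function(r) ncol(r$values), integer(1))
  if (length(unique(n)) != 1L)
    stop("all runs must have the same voxel count", call. = FALSE)
  trs <- vapply(runs, function(r) r$tr_s, numeric(1))
  if (max(trs) - min(trs) > 1e-9)
    stop("all runs must share the repetition time", call. = FALSE)
  structure(list(runs = runs, m = length(runs)), class = "run_set")
}

#' @export
print.run_set <- function(x, ...) {
  cat(sprintf("<run_set> %d runs x %d voxels (T: %s)\n", x$m,
              ncol(x$runs[[1]]$values),
              paste(vapply(x$runs, function(r) nrow(r$values), integer(1)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
length.run_set <- function(x) x$m

# concatenate runs (optionally excluding one fold) into a plain matrix
rs_concat <- function(rs, exclude = NULL) {
  idx <- seq_len(rs$m)
  if (!is.null(exclude)) idx <- idx[idx != exclude]
  do.call(rbind, lapply(rs$runs[idx], function(r) r$values))
}

# apply a timecourse_matrix -> timecourse_matrix function to every run
rs_map <- function(rs, f, ...) {
  run_set(lapply(rs$runs, f, ...))
}

# build a run_set from a list of plain matrices
rs_from_matrices <- function(mats, tr_s, run_ids = NULL, voxel_order = NULL) {
  if (is.null(run_ids)) run_ids <- paste0("run", seq_along(mats))
  run_set(Map(function(m, id)
    timecourse_matrix(m, tr_s = tr_s, run_id = id, voxel_order = voxel_order),
    mats, run_ids))
}
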