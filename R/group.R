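#' One-sample sign-flip permutation test with max-statistic FWE control
#'
#' Nonparametric group inference over subject maps: under the null of
#' symmetrically distributed subject effects around zero, each subject's
#' map may have its sign flipped. For each permutation the voxelwise
#' one-sample t statistic is recomputed and its maximum over voxels
#' recorded; the FWE-corrected p-value of a voxel is the proportion of
#' permutations (identity included, so p >= 1/n) whose max statistic
#' reaches that voxel's observed t. When `2^N <= n_permutations` the full
#' set of sign flips is enumerated exactly; otherwise random flips are
#' drawn from the given seed.
#'
#' @param subject_maps List of >= 2 [brain_map()]s sharing a mask, or an
#'   N x V numeric matrix (subjects x voxels).
#' @param alpha FWE level in (0, 1) (default 0.05).
#' @param n_permutations Permutation budget (default 1000).
#' @param rng_seed RNG seed, mandatory for Monte-Carlo reproducibility.
#' @param alternative `"greater"` (default; dependence > 0, the map
#'   convention) or `"two.sided"` (uses |t| and max |t|).
#' @return An object of class `group_result`: `t` (voxelwise one-sample
#'   t), `p_fwe`, `threshold` (critical max-statistic value at `alpha`),
#'   `n_permutations` (actual count used), `exhaustive`, `seed`, and —
#'   when the input was a list of maps — `t_map` and `p_fwe_map` as
#'   [brain_map()]s.
#' @export
signflip_fwe_test <- function(subject_maps, alpha = 0.05,
                              n_permutations = 1000, rng_seed,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (missing(rng_seed)) stop("`rng_seed` is required", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  mask <- NULL
  if (is.list(subject_maps)) {
    stopifnot(all(vapply(subject_maps, inherits, logical(1), "brain_map")))
    sizes <- vapply(subject_maps, function(m) length(m$values), integer(1))
    if (length(unique(sizes)) != 1L)
      stop("subject maps must share a mask", call. = FALSE)
    mask <- subject_maps[[1]]$mask
    X <- do.call(rbind, lapply(subject_maps, `[[`, "values"))
  } else {
    X <- as.matrix(subject_maps)
  }
  N <- nrow(X)
  if (N < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (!all(is.finite(X)))
    stop("subject maps must be finite at all mask voxels", call. = FALSE)

  exhaustive <- N <= 30 && 2^N <= n_permutations
  S <- if (exhaustive) {
    n_used <- as.integer(2^N)
    vapply(seq_len(N), function(i)
      ifelse(bitwAnd(0:(n_used - 1L), bitwShiftL(1L, i - 1L)) > 0, -1, 1),
      numeric(n_used))
  } else {
    n_used <- as.integer(n_permutations)
    set.seed(rng_seed)
    rbind(rep(1, N),  # identity permutation always in the null
          matrix(sample(c(-1, 1), (n_used - 1L) * N, replace = TRUE),
                 n_used - 1L, N))
  }

  sumsq <- colSums(X^2)
  t_of_signs <- function(Smat) {
    mean_p <- (Smat %*% X) / N                        # perms x voxels
    var_p <- sweep(-mean_p^2, 2L, sumsq / N, "+") * N / (N - 1)
    var_p[var_p < 0] <- 0
    tt <- mean_p / sqrt(var_p / N)
    tt[is.nan(tt)] <- 0   # mean 0 and variance 0: no evidence either way
    tt
  }
  t_all <- t_of_signs(S)
  t_obs <- t_all[which(rowSums(S == 1) == N)[1], ]
  stat_all <- if (alternative == "greater") t_all else abs(t_all)
  stat_obs <- if (alternative == "greater") t_obs else abs(t_obs)
  max_stat <- apply(stat_all, 1L, max)
  p_fwe <- vapply(stat_obs, function(t0) mean(max_stat >= t0), numeric(1))
  threshold <- stats::quantile(max_stat, 1 - alpha, type = 1, names = FALSE)

  res <- list(t = t_obs, p_fwe = p_fwe, threshold = threshold,
              alpha = alpha, n_permutations = nrow(S),
              exhaustive = exhaustive, seed = rng_seed,
              alternative = alternative)
  if (!is.null(mask)) {
    res$t_map <- brain_map(mask, t_obs, label = "group_t")
    res$p_fwe_map <- brain_map(mask, p_fwe, label = "group_p_fwe")
  }
  structure(res, class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf(paste0("<group_result> %d voxels, %d %s permutations, ",
                     "alpha = %.3g, threshold = %.4g, %d significant\n"),
              length(x$t), x$n_permutations,
              if (x$exhaustive) "exhaustive" else "Monte-Carlo",
              x$alpha, x$threshold, sum(x$p_fwe <= x$alpha)))
  invisible(x)
}

#' Write group-test outputs
#'
#' Writes the t and FWE p-value volumes (when maps are attached) and a
#' JSON summary of threshold, alpha, permutation count and seed.
#'
#' @param result A `group_result`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the list of written paths.
#' @export
write_group_result <- function(result, dir, prefix = "group") {
  stopifnot(inherits(result, "group_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(summary = file.path(dir, paste0(prefix, "_summary.json")))
  if (!is.null(result$t_map)) {
    paths$t <- write_brain_map(result$t_map,
                               file.path(dir, paste0(prefix, "_t.nii.gz")))
    paths$p_fwe <- write_brain_map(result$p_fwe_map,
                                   file.path(dir, paste0(prefix, "_pfwe.nii.gz")))
  }
  jsonlite::write_json(list(threshold = result$threshold,
                            alpha = result$alpha,
                            n_permutations = result$n_permutations,
                            exhaustive = result$exhaustive,
                            seed = result$seed,
                            alternative = result$alternative,
                            n_significant = sum(result$p_fwe <= result$alpha)),
                       paths$summary, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
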