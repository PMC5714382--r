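#' Default pipeline configuration
#'
#' Assembles the full analysis configuration with the conventional
#' defaults: 128 s high-pass, 5 CompCor components, optional global-signal
#' and motion regressors, 6 mm searchlight radius, alpha 0.05 group
#' threshold. Values from a YAML/JSON config file override these; explicit
#' `overrides` win over both.
#'
#' @return Nested named list.
#' @export
default_pipeline_config <- function() {
  list(
    paths = list(runs = character(0), seed_mask = NULL, gm_mask = NULL,
                 control_mask = NULL, nuisance = character(0),
                 censor = character(0), out_dir = "mvpd_out"),
    tr_s = 2,
    preprocessing = list(highpass_cutoff_s = 128, compcor_n = 5,
                         use_global_signal = FALSE, use_motion = FALSE),
    mvpd = list(component_mode = "fixed", k_fixed = 3,
                weights = "singular", remove_univariate = FALSE),
    searchlight = list(radius_mm = 6,
                       metric = "mvpd_rbar", exclude_seed = FALSE),
    group = list(alpha = 0.05, n_permutations = 1000, rng_seed = 1)
  )
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Read a pipeline configuration file
#'
#' @param path YAML or JSON file (extension-dispatched); `NULL` gives the
#'   defaults.
#' @param overrides Named list applied on top of the file values.
#' @return Resolved configuration list.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    file_cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    cfg <- merge_config(cfg, file_cfg)
  }
  merge_config(cfg, overrides)
}

write_resolved_config <- function(cfg, dir) {
  cfg$package_version <- as.character(utils::packageVersion("mvpdR"))
  jsonlite::write_json(cfg, file.path(dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

# preprocess one run's region timecourses per the config switches
preprocess_run <- function(ts, cfg, compcor = NULL, extra_nuisance = NULL,
                           censor = NULL) {
  ts <- highpass_filter(ts, cfg$preprocessing$highpass_cutoff_s)
  nuis <- nuisance_set(matrix(0, nrow(ts$values), 0), run_id = ts$run_id)
  if (!is.null(compcor)) nuis <- combine_nuisance(nuis, compcor)
  if (!is.null(extra_nuisance)) nuis <- combine_nuisance(nuis, extra_nuisance)
  ts <- regress_out(ts, nuis)
  if (!is.null(censor)) ts <- apply_censor(ts, censor)
  ts
}

#' Run the subject-level pipeline: preprocess, searchlight, write maps
#'
#' Loads the configured runs and masks, applies matrix-level de-noising
#' (high-pass, CompCor from the control region, optional extra nuisance
#' tables, censoring), sweeps the searchlight, and writes one NIfTI map
#' per metric/dimension plus a TSV manifest, a resolved-config snapshot
#' and the package version into the output directory.
#'
#' @param config A resolved configuration list
#'   ([read_pipeline_config()]).
#' @return Invisibly, a list with `maps` (the [brain_map()]s) and
#'   `manifest` (data.frame of written files).
#' @export
mvpd_subject <- function(config) {
  p <- config$paths
  if (length(p$runs) < 2L)
    stop("need at least 2 runs for leave-one-run-out", call. = FALSE)
  for (f in c(p$runs, p$seed_mask, p$gm_mask, p$control_mask,
              p$nuisance, p$censor))
    if (!is.null(f) && !file.exists(f))
      stop("input not found: ", f, call. = FALSE)
  if (is.null(p$seed_mask) || is.null(p$gm_mask))
    stop("`seed_mask` and `gm_mask` are required", call. = FALSE)

  gm_mask <- read_mask(p$gm_mask)
  seed_mask <- read_mask(p$seed_mask, grid = gm_mask$grid)
  control_mask <- if (!is.null(p$control_mask))
    read_mask(p$control_mask, grid = gm_mask$grid) else NULL

  m <- length(p$runs)
  vols <- vector("list", m)
  for (i in seq_len(m)) {
    arr <- load_volume_array(p$runs[[i]])
    run_id <- paste0("run", i)
    ts_gm <- load_run_timecourses(arr, gm_mask, config$tr_s, run_id)
    compcor <- NULL
    if (!is.null(control_mask)) {
      ctrl <- load_run_timecourses(arr, control_mask, config$tr_s, run_id)
      ctrl <- highpass_filter(ctrl, config$preprocessing$highpass_cutoff_s)
      compcor <- compcor_components(ctrl, config$preprocessing$compcor_n)
    }
    extra <- if (length(p$nuisance) >= i && nzchar(p$nuisance[i]))
      read_nuisance_tsv(p$nuisance[i], run_id) else NULL
    cens <- if (length(p$censor) >= i && nzchar(p$censor[i]))
      read_censor_tsv(p$censor[i], run_id) else NULL
    ts_gm <- preprocess_run(ts_gm, config, compcor, extra, cens)
    # rebuild the cleaned 4D volume so the searchlight sees cleaned data
    flat <- matrix(NaN, prod(gm_mask$grid$dims), nrow(ts_gm$values))
    flat[mask_linear_index(gm_mask), ] <- t(ts_gm$values)
    flat[is.nan(flat)] <- 0
    vols[[i]] <- array(flat, c(gm_mask$grid$dims, nrow(ts_gm$values)))
  }

  sl_cfg <- searchlight_config(
    radius_mm = config$searchlight$radius_mm,
    metric = config$searchlight$metric,
    component_mode = config$mvpd$component_mode,
    k_fixed = config$mvpd$k_fixed,
    weights = config$mvpd$weights,
    remove_univariate = config$mvpd$remove_univariate,
    exclude_seed = config$searchlight$exclude_seed)
  maps <- run_searchlight(vols, gm_mask, seed_mask, sl_cfg,
                          tr_s = config$tr_s)
  if (inherits(maps, "brain_map")) maps <- list(maps)

  out <- p$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- do.call(rbind, lapply(maps, function(mp) {
    f <- file.path(out, paste0(mp$label, ".nii.gz"))
    write_brain_map(mp, f)
    data.frame(label = mp$label, file = f, metric = sl_cfg$metric,
               component_mode = sl_cfg$component_mode,
               k_fixed = sl_cfg$k_fixed, n_runs = m)
  }))
  utils::write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_resolved_config(config, out)
  invisible(list(maps = maps, manifest = manifest))
}

#' Run group-level inference over subject maps
#'
#' Loads per-subject statistic volumes on a shared mask, runs the
#' sign-flip max-statistic permutation test, and writes t/p volumes plus a
#' JSON summary.
#'
#' @param config Resolved configuration list (uses `group$alpha`,
#'   `group$n_permutations`, `group$rng_seed`, `paths$gm_mask`,
#'   `paths$out_dir`).
#' @param map_paths Character vector of >= 2 subject map files.
#' @return Invisibly, the `group_result`.
#' @export
mvpd_group <- function(config, map_paths) {
  if (length(map_paths) < 2L)
    stop("need at least 2 subject maps", call. = FALSE)
  mask <- if (!is.null(config$paths$gm_mask)) read_mask(config$paths$gm_mask)
          else NULL
  maps <- lapply(map_paths, function(f) read_brain_map(f, mask = mask))
  res <- signflip_fwe_test(maps, alpha = config$group$alpha,
                           n_permutations = config$group$n_permutations,
                           rng_seed = config$group$rng_seed)
  out <- config$paths$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_group_result(res, out)
  write_resolved_config(config, out)
  invisible(res)
}
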