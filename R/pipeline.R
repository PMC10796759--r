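#' Pipeline configuration
#'
#' A single structured configuration for [run_pipeline()]: the synthetic study
#' layout (specimen labels), phantom and noise settings, and every stage
#' default (registration, segmentation threshold, profile step, gray-value
#' conversion, window filter, correlation channel). All values are recorded in
#' the run manifest.
#'
#' @param seed Base integer seed; every specimen derives its own seed from it.
#' @param specimens Data frame with columns `individual`, `region`, `level`
#'   (one row per synthetic specimen).
#' @param shape,spacing Phantom grid (see [make_phantom()]).
#' @param trabecular_sd,hu_noise_sd Phantom texture and white-noise settings
#'   (HU).
#' @param misalignment_max Max |rotation| (deg) and |translation| (mm) of the
#'   random pre/post misalignment.
#' @param force_sd,ar1 Force-noise settings (N, AR(1) coefficient).
#' @param link Affine density-to-force link (list: `intercept`, `slope`).
#' @param insertion_offset Air travel before bone contact (mm).
#' @param register If `TRUE` run [register_rigid()]; otherwise undo the
#'   misalignment from the recorded truth (useful to isolate later stages).
#' @param use_true_path If `TRUE` skip canal estimation and profile along the
#'   true canal (validation mode).
#' @param threshold_hu Difference threshold for [segment_canal()].
#' @param ds,disk_points Profile sampling (see [extract_profile()]).
#' @param pad_start Air padding of the profiled path (mm), so insertion
#'   detection has a baseline.
#' @param gv_offset,gv_clamp Gray-value conversion (see [hu_to_gv()]).
#' @param window_half_width Half-width (mm) of [windowed_stats()], or `NULL`
#'   to skip the filter.
#' @param correlation_channel Profile channel correlated against force
#'   (default `"gv_max"`; the windowed maxima correlate most strongly with the
#'   force record).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            specimens = tibble::tibble(individual = "A",
                                                       region = "T",
                                                       level = "T11"),
                            shape = c(128, 128, 128),
                            spacing = c(0.5, 0.5, 0.5),
                            trabecular_sd = 60, hu_noise_sd = 0,
                            misalignment_max = c(3, 2.5),
                            force_sd = 0.15, ar1 = 0.8,
                            link = list(intercept = 0.2, slope = 0.0025),
                            insertion_offset = 1.3,
                            register = TRUE, use_true_path = FALSE,
                            threshold_hu = 400, ds = 0.1, disk_points = 13,
                            pad_start = 3,
                            gv_offset = 1026, gv_clamp = c(0, 4096),
                            window_half_width = 0.2,
                            correlation_channel = "gv_max") {
  cfg <- as.list(environment())
  cfg$specimens <- tibble::as_tibble(specimens)
  stopifnot(all(c("individual", "region", "level") %in%
                names(cfg$specimens)))
  structure(cfg, class = "pipeline_config")
}

stage <- function(name, specimen, warnings_env, code) {
  withCallingHandlers(
    tryCatch(code, error = function(e) {
      rlang::abort(sprintf("stage '%s' failed for specimen %s: %s", name,
                           specimen, conditionMessage(e)), parent = e)
    }),
    warning = function(w) {
      warnings_env$log <- c(warnings_env$log,
                            sprintf("[%s | %s] %s", specimen, name,
                                    conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
}

#' Run the full synthetic pipeline
#'
#' Executes phantom generation, canal carving with misalignment, registration,
#' difference-image canal estimation, profile extraction with gray-value
#' conversion and window filtering, force simulation from the ground-truth
#' profile, insertion-point alignment, and grouped correlation — one specimen
#' per row of `config$specimens`. Identical config and seed give identical
#' numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, per-specimen profiles and
#'   aligned pairs (CSV), the results table (CSV + JSON), truth sidecars and a
#'   run manifest (JSON) are written there.
#' @return List of class `pipeline_run` with elements `results` (tibble from
#'   [grouped_correlations()]), `pairs`, `profiles`, `truths`, and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  wenv <- new.env(); wenv$log <- character(0)
  pairs <- list(); profiles <- list(); truths <- list()

  for (i in seq_len(nrow(config$specimens))) {
    sp <- config$specimens[i, ]
    id <- sprintf("%s_%s", sp$individual, sp$level)
    seed_i <- config$seed + 101L * i
    meta <- specimen_meta(sp$individual, sp$region, sp$level)

    ph <- stage("phantom", id, wenv,
      make_phantom(shape = config$shape, spacing = config$spacing,
                   seed = seed_i, trabecular_sd = config$trabecular_sd,
                   hu_noise_sd = config$hu_noise_sd,
                   misalignment_max = config$misalignment_max,
                   link = config$link,
                   noise = list(hu_sd = config$hu_noise_sd,
                                force_sd = config$force_sd,
                                ar1 = config$ar1),
                   insertion_offset = config$insertion_offset))
    pre <- ph$volume; truth <- ph$truth
    post <- stage("carve", id, wenv, carve_canal(pre, truth))

    correction <- if (config$register)
      stage("register", id, wenv, register_rigid(pre, post))
    else invert_transform(truth$misalignment)
    post_reg <- stage("resample", id, wenv,
                      resample_volume(post, correction))

    path_est <- if (config$use_true_path) truth$path else {
      diff <- stage("difference", id, wenv, difference_volume(pre, post_reg))
      vox <- stage("segment", id, wenv,
                   segment_canal(diff, config$threshold_hu))
      p0 <- stage("axis_pca", id, wenv,
                  estimate_axis_pca(vox, radius = truth$path$radius))
      stage("refine", id, wenv,
            refine_endpoints(diff, p0, disk_points = config$disk_points))
    }

    prof <- stage("profile", id, wenv, {
      p <- extract_profile(pre, extend_path(path_est, config$pad_start),
                           ds = config$ds,
                           disk_points = config$disk_points, meta = meta)
      p <- profile_to_gv(p, config$gv_offset, config$gv_clamp)
      if (!is.null(config$window_half_width))
        p <- windowed_stats(p, config$window_half_width)
      p
    })

    force <- stage("force", id, wenv, {
      tp <- extract_profile(pre,
                            extend_path(truth$path, config$pad_start),
                            ds = config$ds,
                            disk_points = config$disk_points)
      tp <- profile_to_gv(tp, config$gv_offset, config$gv_clamp)
      simulate_force_trace(tp, truth)
    })

    pair <- stage("align", id, wenv,
                  align_pair(prof, trace_to_displacement(force),
                             channel = config$correlation_channel))
    pairs[[id]] <- pair
    profiles[[id]] <- prof
    truths[[id]] <- truth
  }

  results <- grouped_correlations(pairs)
  manifest <- list(
    package_version = as.character(utils::packageVersion("drillprofile")),
    seed = config$seed,
    config = unclass(config),
    warnings = wenv$log)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (id in names(pairs)) {
      utils::write.csv(as.data.frame(profiles[[id]]),
                       file.path(out_dir, sprintf("profile_%s.csv", id)),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(pairs[[id]]),
                       file.path(out_dir, sprintf("pair_%s.csv", id)),
                       row.names = FALSE)
      write_phantom_truth(truths[[id]],
                          file.path(out_dir, sprintf("truth_%s.json", id)))
    }
    write_results(results, csv = file.path(out_dir, "results.csv"),
                  json = file.path(out_dir, "results.json"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, na = "null")
  }
  structure(list(results = results, pairs = pairs, profiles = profiles,
                 truths = truths, manifest = manifest),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d specimens, %d result rows\n",
              length(x$pairs), nrow(x$results)))
  print(x$results)
  invisible(x)
}
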