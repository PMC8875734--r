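# File-based pipeline runs: each run writes its outputs plus a manifest
# (inputs, effective config, seeds, package version, per-stage status) that
# suffices to reproduce the run bit-identically. No command mutates its
# inputs; all randomness is seeded.

manifest_new <- function(command, inputs, config = NULL, seed = NULL) {
  list(tool = "icgquant",
       version = as.character(utils::packageVersion("icgquant")),
       command = command, inputs = inputs, config = config, seed = seed,
       stages = list(), warnings = list())
}

manifest_write <- function(manifest, out_dir) {
  manifest$.out_dir <- NULL
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
}

run_stage <- function(manifest, name, expr) {
  res <- tryCatch(force(expr), error = function(e) e)
  if (inherits(res, "error")) {
    manifest$stages[[name]] <- list(status = "failed", message = conditionMessage(res))
    manifest_write(manifest, manifest$.out_dir)
    stop(res)
  }
  manifest$stages[[name]] <- list(status = "ok")
  assign("manifest", manifest, envir = parent.frame())
  res
}

#' Quantify a recording end to end
#'
#' Runs preprocessing (flat-field correction when a profile is supplied),
#' ROI trace extraction, per-location quantification and - when the
#' annotations carry a centerline and calibration - demarcation and
#' watershed geometry. Accepts either a recording (TIFF stack or frame
#' directory, with `rois_path`) or a pre-extracted traces CSV. Writes
#' `results.json`, per-trace CSVs (raw, smoothed, derivative) and
#' `manifest.json` into `out_dir`.
#'
#' @param input_path Recording (TIFF / frame directory) or traces CSV.
#' @param rois_path Annotation JSON ([read_roi_set()] schema); required for
#'   recordings, ignored for trace CSVs.
#' @param out_dir Output directory (created if needed).
#' @param frame_rate Hz; required for recordings.
#' @param profile_path Optional illumination profile
#'   ([write_illumination_profile()] format).
#' @param config A [quant_config()], or a path to a JSON/YAML config.
#' @param threshold_fraction Demarcation threshold fraction (see
#'   [detect_demarcation()]).
#' @return Invisibly, a list with `params`, `geometry`, `traces`,
#'   `manifest`.
#' @export
run_quantify <- function(input_path, rois_path = NULL, out_dir,
                         frame_rate = 25, profile_path = NULL,
                         config = quant_config(), threshold_fraction = 0.25) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(config)) config <- read_quant_config(config)
  manifest <- manifest_new("quantify",
                           inputs = list(input = input_path, rois = rois_path,
                                         profile = profile_path,
                                         frame_rate = frame_rate),
                           config = unclass(config))
  manifest$.out_dir <- out_dir

  is_csv <- !dir.exists(input_path) &&
    tolower(tools::file_ext(input_path)) == "csv"
  geometry <- NULL
  if (is_csv) {
    traces <- run_stage(manifest, "load_traces", read_traces_csv(input_path))
  } else {
    rois <- run_stage(manifest, "load_annotations", {
      if (is.null(rois_path)) abort_input("rois_path is required for recordings")
      read_roi_set(rois_path)
    })
    stack <- run_stage(manifest, "load_stack", read_frame_stack(input_path, frame_rate))
    if (!is.null(profile_path)) {
      stack <- run_stage(manifest, "flatfield", {
        profile <- read_illumination_profile(profile_path)
        correct_illumination(stack, profile)
      })
    }
    traces <- run_stage(manifest, "extract_traces", extract_traces(stack, rois))
    if (!is.null(rois$centerline) && !is.null(rois$calibration_points)) {
      geometry <- run_stage(manifest, "geometry", {
        cp <- rois$calibration_points
        calib <- calibrate_pixels(cp$point_a, cp$point_b, cp$physical_cm)
        late <- late_phase_image(stack)
        g <- detect_demarcation(late, rois$centerline, calib, threshold_fraction)
        if (!is.null(rois$watershed_vertex)) {
          ws_point <- rois$centerline[rois$watershed_vertex + 1L, ]
          g$watershed_to_fundus_cm <-
            measure_watershed_distance(ws_point, rois$centerline, calib)
        }
        g
      })
    }
  }

  results <- run_stage(manifest, "quantify", lapply(traces, quantify_trace, config = config))
  processed <- lapply(results, attr, "trace")
  for (p in results) {
    if (p$influx_detected && p$window_truncated)
      manifest$warnings <- c(manifest$warnings,
                             sprintf("location %d: parameter window truncated at end of recording",
                                     p$location_id))
    if (!p$influx_detected)
      manifest$warnings <- c(manifest$warnings,
                             sprintf("location %d: no influx detected", p$location_id))
  }

  run_stage(manifest, "write_outputs", {
    write_results(results, geometry, file.path(out_dir, "results.json"))
    write_traces_csv(processed, file.path(out_dir, "traces_raw.csv"), "raw")
    write_traces_csv(processed, file.path(out_dir, "traces_smoothed.csv"), "smoothed")
    write_traces_csv(processed, file.path(out_dir, "traces_derivative.csv"), "derivative")
  })
  manifest$.out_dir <- NULL
  manifest_write(manifest, out_dir)
  invisible(list(params = results, geometry = geometry, traces = processed,
                 manifest = manifest))
}

#' Generate phantom artifacts on disk
#'
#' Renders a [generate_phantom_stack()] scene and writes `stack.tif`,
#' `uniform_target.tif`, `profile.tif` (flat-field fitted from the uniform
#' target), `annotations.json`, `ground_truth.json` and `manifest.json`.
#' Re-running with the same spec and seed reproduces every file
#' byte-identically.
#'
#' @param spec A [phantom_spec()].
#' @param seed Optional integer overriding the spec's kinetics seed.
#' @param out_dir Output directory.
#' @return Invisibly, the [generate_phantom_stack()] result.
#' @export
run_simulate <- function(spec = phantom_spec(), seed = NULL, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(seed)) spec$kinetics$seed <- as.integer(seed)
  manifest <- manifest_new("simulate", inputs = list(),
                           seed = spec$kinetics$seed)
  manifest$.out_dir <- out_dir
  phantom <- run_stage(manifest, "render", generate_phantom_stack(spec))
  run_stage(manifest, "write_outputs", {
    write_frame_stack(phantom$stack, file.path(out_dir, "stack.tif"))
    write_frame_stack(phantom$uniform_stack, file.path(out_dir, "uniform_target.tif"))
    profile <- fit_illumination_profile(phantom$uniform_stack)
    write_illumination_profile(profile, file.path(out_dir, "profile.tif"))
    write_roi_set(phantom$annotations, file.path(out_dir, "annotations.json"))
    jsonlite::write_json(phantom$truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  manifest$.out_dir <- NULL
  manifest_write(manifest, out_dir)
  invisible(phantom)
}

#' Run the cohort statistics layer on a cohort CSV
#'
#' Writes `stats.json` (machine-readable report) and `report.txt` (human
#' summary) into `out_dir`.
#'
#' @param cohort_path Cohort CSV ([read_cohort_csv()] schema).
#' @param out_dir Output directory.
#' @param slope_threshold,distance_threshold Risk-rule thresholds (see
#'   [classify_risk()]).
#' @return Invisibly, the [cohort_report()].
#' @export
run_stats <- function(cohort_path, out_dir, slope_threshold = 0.2,
                      distance_threshold = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- manifest_new("stats", inputs = list(cohort = cohort_path),
                           config = list(slope_threshold = slope_threshold,
                                         distance_threshold = distance_threshold))
  manifest$.out_dir <- out_dir
  cohort <- run_stage(manifest, "load_cohort", read_cohort_csv(cohort_path))
  report <- run_stage(manifest, "statistics",
                      cohort_report(cohort, slope_threshold, distance_threshold))
  run_stage(manifest, "write_outputs", {
    jsonlite::write_json(unclass(report), file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE, force = TRUE)
    con <- file(file.path(out_dir, "report.txt"), "w")
    sink(con); print(report); sink(); close(con)
  })
  manifest$.out_dir <- NULL
  manifest_write(manifest, out_dir)
  invisible(report)
}
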