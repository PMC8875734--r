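#' Frame stack: a time-ordered fluorescence recording
#'
#' Container for a multi-frame near-infrared recording. Frames are stored as
#' a 3-D array indexed `[frame, row, col]`; intensities are arbitrary units
#' (8-bit cameras give 0-255) and must be finite and non-negative.
#'
#' @param frames 3-D numeric array, time x height x width.
#' @param frame_rate Frames per second (Hz), > 0.
#' @param t0_offset Seconds between dye administration and the first frame.
#'   Stored for provenance; the package's time axis always starts at the
#'   first recorded frame.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_rate, t0_offset = 0) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    abort_input("frames must be a 3-D array (time x height x width)")
  if (!all(is.finite(frames)) || any(frames < 0))
    abort_input("frame intensities must be finite and >= 0")
  stopifnot_scalar_pos(frame_rate, "frame_rate")
  if (!is.numeric(t0_offset) || length(t0_offset) != 1L || t0_offset < 0)
    abort_input("t0_offset must be a single non-negative number")
  structure(list(frames = frames, frame_rate = frame_rate, t0_offset = t0_offset),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %dx%d px @ %g Hz (%.1f s)\n",
              d[1], d[2], d[3], x$frame_rate, d[1] / x$frame_rate))
  invisible(x)
}

#' Frame times of a stack (seconds since recording start)
#' @param stack A [frame_stack()].
#' @return Numeric vector, `t[i] = (i - 1) / frame_rate`.
#' @export
frame_times <- function(stack) {
  (seq_len(dim(stack$frames)[1]) - 1) / stack$frame_rate
}

#' Read a recording from a multi-page TIFF or a directory of frames
#'
#' Integer-valued images are preserved bit-exactly. A directory is read as a
#' lexicographically ordered sequence of single-frame PNG or TIFF images
#' (PNG samples are mapped back to their 8-bit values). A floating-point
#' stack written by [write_frame_stack()] carries a JSON sidecar with its
#' intensity scale, which is applied transparently on read.
#'
#' @param path Multi-page TIFF file, or directory of per-frame images.
#' @param frame_rate Acquisition rate in Hz (must be supplied; recordings do
#'   not embed it).
#' @param t0_offset See [frame_stack()].
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(path, frame_rate, t0_offset = 0) {
  stopifnot_scalar_pos(frame_rate, "frame_rate")
  if (!file.exists(path)) abort_input("no such file or directory: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) abort_input("no frame images found in ", path)
    mats <- lapply(files, read_single_frame)
  } else {
    mats <- read_tiff_pages(path)
  }
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    abort_input("inconsistent frame dimensions across the recording")
  frames <- array(0, dim = c(length(mats), dims[1, 1], dims[2, 1]))
  for (i in seq_along(mats)) frames[i, , ] <- mats[[i]]
  scale <- read_intensity_sidecar(path)
  if (!is.null(scale)) frames <- frames * scale
  frame_stack(frames, frame_rate, t0_offset)
}

read_tiff_pages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, as_gray_matrix)
}

read_single_frame <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext == "png") {
    img <- png::readPNG(file)
    round(as_gray_matrix(img) * 255)
  } else {
    as_gray_matrix(tiff::readTIFF(file, as.is = TRUE))
  }
}

as_gray_matrix <- function(img) {
  if (length(dim(img)) == 3L) img <- img[, , 1]
  if (!is.matrix(img)) abort_input("frame image is not a 2-D intensity map")
  img
}

read_intensity_sidecar <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) return(NULL)
  meta <- jsonlite::read_json(sidecar)
  meta$intensity_scale %||% NULL
}

#' Write a recording as a multi-page TIFF
#'
#' Stacks whose intensities are all integers in 0-255 are written as 8-bit
#' pages and round-trip bit-exactly. Other stacks are written as 32-bit
#' pages scaled into the unit interval, with the scale recorded in a JSON
#' sidecar (`<path>.json`) that [read_frame_stack()] applies on read.
#'
#' @param stack A [frame_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  f <- stack$frames
  n <- dim(f)[1]
  is_u8 <- all(f == round(f)) && max(f) <= 255
  sidecar <- paste0(path, ".json")
  if (is_u8) {
    pages <- lapply(seq_len(n), function(i) f[i, , ] / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
    if (file.exists(sidecar)) unlink(sidecar)
  } else {
    scale <- max(f, 1)
    pages <- lapply(seq_len(n), function(i) f[i, , ] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    jsonlite::write_json(list(intensity_scale = scale, frame_rate = stack$frame_rate),
                         sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Time-intensity trace for one location
#'
#' The working object of the quantification algorithm: the mean ROI
#' fluorescence of one anatomical location sampled on the recording's
#' uniform time base. `smoothed` and `derivative` stay `NULL` until
#' [smooth_trace()] / [pointwise_derivative()] fill them in.
#'
#' @param location_id Integer location (1 = conduit base below watershed,
#'   2 = watershed, 3 = above watershed, 4 = fundus).
#' @param time Seconds since recording start; strictly increasing, uniform.
#' @param raw Raw mean intensities, same length as `time`.
#' @param smoothed,derivative Optional computed series.
#' @return An object of class `intensity_trace`.
#' @export
intensity_trace <- function(location_id, time, raw, smoothed = NULL, derivative = NULL) {
  if (length(time) < 2L) abort_input("a trace needs at least 2 samples")
  if (length(raw) != length(time)) abort_input("time and raw lengths differ")
  if (any(!is.finite(time)) || any(!is.finite(raw)))
    abort_input("trace contains non-finite values")
  dt <- diff(time)
  if (any(dt <= 0)) abort_input("time must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9 * max(dt))
    abort_input("time samples are not uniformly spaced")
  for (s in list(smoothed, derivative))
    if (!is.null(s) && length(s) != length(time))
      abort_input("computed series length differs from time")
  structure(list(location_id = as.integer(location_id), time = time, raw = raw,
                 smoothed = smoothed, derivative = derivative),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("<intensity_trace> location %d, %d samples @ %.4g s%s%s\n",
              x$location_id, length(x$time), x$time[2] - x$time[1],
              if (is.null(x$smoothed)) "" else ", smoothed",
              if (is.null(x$derivative)) "" else ", derivative"))
  invisible(x)
}

trace_dt <- function(trace) trace$time[2] - trace$time[1]

#' Read time-intensity traces from CSV
#'
#' Expects a header `time_s, loc1, ..., loc4`; any subset of the location
#' columns is accepted (location 1 is missing when the conduit base lies
#' intra-thoracically and cannot be imaged).
#'
#' @param path CSV file path.
#' @return List of [intensity_trace()] objects, in location order.
#' @export
read_traces_csv <- function(path) {
  if (!file.exists(path)) abort_input("no such file: ", path)
  df <- read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) abort_input("traces CSV must have a time_s column")
  loc_cols <- grep("^loc[1-4]$", names(df), value = TRUE)
  if (length(loc_cols) == 0L) abort_input("traces CSV has no loc1..loc4 columns")
  if (anyNA(df)) abort_input("traces CSV contains missing or non-numeric cells")
  lapply(loc_cols, function(cl) {
    intensity_trace(as.integer(sub("loc", "", cl)), df$time_s, df[[cl]])
  })
}

#' Write time-intensity traces to CSV
#'
#' @param traces List of [intensity_trace()] sharing one time base.
#' @param path Output path.
#' @param series Which series to write (`"raw"`, `"smoothed"` or
#'   `"derivative"`); the column layout is the [read_traces_csv()] schema.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path, series = "raw") {
  if (length(traces) == 0L) abort_input("no traces to write")
  df <- data.frame(time_s = traces[[1]]$time)
  for (tr in traces) {
    v <- tr[[series]]
    if (is.null(v)) abort_input("series '", series, "' absent for location ", tr$location_id)
    df[[paste0("loc", tr$location_id)]] <- v
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Quantification configuration
#'
#' All tunables of the trace-quantification algorithm with their defaults:
#' a 21-sample robust local-regression span, outlier rejection at 6x the
#' robust residual scale, derivative noise statistics over the first 10 s,
#' influx when the derivative exceeds the noise mean by 5.5 sigma for
#' `sustain_samples` consecutive samples, a 10 s F_slope window and a 50 s
#' F_max window anchored at the influx timepoint.
#'
#' @param smoothing_span Samples per local-regression window (forced odd).
#' @param robust_cutoff Residual-scale multiples beyond which samples get
#'   zero weight during robust reweighting.
#' @param noise_window Seconds of baseline used for derivative noise stats.
#' @param influx_k Sigma multiples of the influx threshold.
#' @param slope_window Seconds averaged for F_slope.
#' @param fmax_window Seconds searched for F_max.
#' @param sustain_samples Consecutive supra-threshold samples required for a
#'   detection (1 reproduces the literal single-sample criterion).
#' @param robust_iterations Robust reweighting passes after the initial fit.
#' @param robust_scale `"mad"` (median absolute residual, default) or `"sd"`
#'   for the residual scale estimate.
#' @param fmax_series `"smoothed"` (default) or `"raw"`: series maximised
#'   for F_max.
#' @param sigma_floor_frac Fraction of the trace's intensity range used as a
#'   floor on sigma_noise, guarding noiseless degenerate baselines.
#' @return An object of class `quant_config`.
#' @export
quant_config <- function(smoothing_span = 21, robust_cutoff = 6, noise_window = 10,
                         influx_k = 5.5, slope_window = 10, fmax_window = 50,
                         sustain_samples = 3, robust_iterations = 5,
                         robust_scale = c("mad", "sd"),
                         fmax_series = c("smoothed", "raw"),
                         sigma_floor_frac = 1e-6) {
  for (nm in c("smoothing_span", "robust_cutoff", "noise_window", "influx_k",
               "slope_window", "fmax_window", "sustain_samples", "sigma_floor_frac"))
    stopifnot_scalar_pos(get(nm), nm)
  smoothing_span <- as.integer(smoothing_span)
  if (smoothing_span %% 2L == 0L) smoothing_span <- smoothing_span + 1L
  structure(list(smoothing_span = smoothing_span, robust_cutoff = robust_cutoff,
                 noise_window = noise_window, influx_k = influx_k,
                 slope_window = slope_window, fmax_window = fmax_window,
                 sustain_samples = as.integer(sustain_samples),
                 robust_iterations = as.integer(robust_iterations),
                 robust_scale = match.arg(robust_scale),
                 fmax_series = match.arg(fmax_series),
                 sigma_floor_frac = sigma_floor_frac),
            class = "quant_config")
}

#' Read a quantification configuration from JSON or YAML
#' @param path File ending in `.json`, `.yaml` or `.yml`.
#' @return A [quant_config()]; absent fields keep their defaults.
#' @export
read_quant_config <- function(path) {
  if (!file.exists(path)) abort_input("no such config file: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      abort_input("the yaml package is needed to read YAML configs")
    yaml::read_yaml(path)
  } else abort_input("config must be .json or .yaml")
  known <- names(formals(quant_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) abort_input("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(quant_config, vals)
}

#' Per-location perfusion parameters
#'
#' Holds the three perfusion parameters of one location. When no influx was
#' detected, `tau`, `f_max` and `f_slope` carry `NA` and `influx_detected`
#' is `FALSE`. `window_truncated` flags that the F_slope or F_max window ran
#' past the end of the recording.
#'
#' @param location_id Integer location id.
#' @param tau Influx timepoint, seconds since recording start (or `NA`).
#' @param f_max Maximal intensity over the F_max window (or `NA`).
#' @param f_slope Mean derivative over the F_slope window, intensity/s (or `NA`).
#' @param influx_detected Logical flag.
#' @param window_truncated Logical flag.
#' @return An object of class `perfusion_params`.
#' @export
perfusion_params <- function(location_id, tau = UNDETECTED, f_max = UNDETECTED,
                             f_slope = UNDETECTED, influx_detected = !is.na(tau),
                             window_truncated = FALSE) {
  if (!influx_detected && !(is.na(tau) && is.na(f_max) && is.na(f_slope)))
    abort_input("undetected influx must carry NA for tau, f_max and f_slope")
  structure(list(location_id = as.integer(location_id), tau = tau, f_max = f_max,
                 f_slope = f_slope, influx_detected = influx_detected,
                 window_truncated = window_truncated),
            class = "perfusion_params")
}

#' @export
print.perfusion_params <- function(x, ...) {
  if (x$influx_detected) {
    cat(sprintf("<perfusion_params> loc %d: tau = %.3g s, F_max = %.4g, F_slope = %.4g/s%s\n",
                x$location_id, x$tau, x$f_max, x$f_slope,
                if (x$window_truncated) " [window truncated]" else ""))
  } else {
    cat(sprintf("<perfusion_params> loc %d: no influx detected\n", x$location_id))
  }
  invisible(x)
}

# jsonlite maps NA to null; force plain scalars for deterministic output.
param_to_list <- function(p) {
  list(location = p$location_id,
       tau = if (is.na(p$tau)) NULL else p$tau,
       f_max = if (is.na(p$f_max)) NULL else p$f_max,
       f_slope = if (is.na(p$f_slope)) NULL else p$f_slope,
       influx_detected = p$influx_detected,
       window_truncated = p$window_truncated)
}

#' Write quantification results as JSON
#'
#' One object per location (tau, F_max, F_slope and flags, `null` for
#' undetected sentinels) plus an optional geometry block, under a schema
#' version field with deterministic key order. Writing, re-reading with
#' [read_results()] and writing again is byte-identical.
#'
#' @param params List of [perfusion_params()], at least one.
#' @param geometry A [geometry_measures()] or `NULL`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_results <- function(params, geometry = NULL, path) {
  if (length(params) == 0L) abort_input("at least one location result is required")
  doc <- list(schema_version = 1L,
              locations = lapply(params, param_to_list))
  if (!is.null(geometry)) {
    doc$geometry <- list(demarcation_found = geometry$demarcation_found,
                         demarcation_to_fundus_cm = geometry$demarcation_to_fundus_cm,
                         watershed_to_fundus_cm = geometry$watershed_to_fundus_cm)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a results JSON written by [write_results()]
#' @param path JSON path.
#' @return List with `params` (list of [perfusion_params()]) and `geometry`
#'   (list or `NULL`).
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort_input("no such file: ", path)
  doc <- jsonlite::read_json(path)
  params <- lapply(doc$locations, function(l) {
    perfusion_params(l$location,
                     tau = l$tau %||% UNDETECTED,
                     f_max = l$f_max %||% UNDETECTED,
                     f_slope = l$f_slope %||% UNDETECTED,
                     influx_detected = isTRUE(l$influx_detected),
                     window_truncated = isTRUE(l$window_truncated))
  })
  geometry <- if (is.null(doc$geometry)) NULL else {
    geometry_measures(demarcation_found = isTRUE(doc$geometry$demarcation_found),
                      demarcation_to_fundus_cm = doc$geometry$demarcation_to_fundus_cm,
                      watershed_to_fundus_cm = doc$geometry$watershed_to_fundus_cm %||% NA_real_)
  }
  list(params = params, geometry = geometry)
}

#' ROI set and scene annotations
#'
#' The per-recording annotation object: one circular ROI per anatomical
#' location, and optionally the conduit centerline (ordered base to fundus
#' tip), the watershed vertex index on it, and the two ruler points used for
#' pixel calibration. All pixel coordinates are 0-based `(row, col)` with
#' row 0 at the image top.
#'
#' @param rois List of `list(location, label, center = c(row, col), area)`.
#' @param centerline Optional n x 2 matrix of `(row, col)` vertices.
#' @param watershed_vertex Optional 0-based index into the centerline.
#' @param calibration_points Optional
#'   `list(point_a = c(row, col), point_b = c(row, col), physical_cm = x)`.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(rois, centerline = NULL, watershed_vertex = NULL,
                    calibration_points = NULL) {
  if (length(rois) == 0L) abort_input("an ROI set needs at least one ROI")
  locs <- vapply(rois, function(r) as.integer(r$location), integer(1))
  if (anyDuplicated(locs)) abort_input("duplicate location ids in ROI set")
  if (!all(locs %in% 1:4)) abort_input("location ids must be in 1..4")
  for (r in rois) {
    if (length(r$center) != 2L) abort_input("ROI centers must be (row, col) pairs")
    if (r$area < 1) abort_input("ROI area must be >= 1 pixel")
  }
  if (!is.null(centerline)) {
    centerline <- as.matrix(centerline)
    if (ncol(centerline) != 2L || nrow(centerline) < 2L)
      abort_input("centerline must be an n x 2 matrix with n >= 2")
  }
  structure(list(rois = rois[order(locs)], centerline = centerline,
                 watershed_vertex = watershed_vertex,
                 calibration_points = calibration_points),
            class = "roi_set")
}

#' Read ROI/scene annotations from JSON
#' @param path JSON path with fields `rois` and optional `centerline`,
#'   `watershed_vertex`, `calibration`.
#' @return A [roi_set()].
#' @export
read_roi_set <- function(path) {
  if (!file.exists(path)) abort_input("no such file: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$rois)) abort_input("annotation JSON lacks a rois field")
  rois <- lapply(doc$rois, function(r) {
    list(location = r$location, label = r$label %||% "",
         center = as.numeric(unlist(r$center)), area = r$area)
  })
  centerline <- if (is.null(doc$centerline)) NULL else
    do.call(rbind, lapply(doc$centerline, function(p) as.numeric(unlist(p))))
  calib <- if (is.null(doc$calibration)) NULL else
    list(point_a = as.numeric(unlist(doc$calibration$point_a)),
         point_b = as.numeric(unlist(doc$calibration$point_b)),
         physical_cm = doc$calibration$physical_cm)
  roi_set(rois, centerline, doc$watershed_vertex %||% NULL, calib)
}

#' Write ROI/scene annotations to JSON
#' @param rois A [roi_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_set <- function(rois, path) {
  doc <- list(rois = lapply(rois$rois, function(r)
    list(location = r$location, label = r$label, center = r$center, area = r$area)))
  if (!is.null(rois$centerline))
    doc$centerline <- lapply(seq_len(nrow(rois$centerline)),
                             function(i) rois$centerline[i, ])
  if (!is.null(rois$watershed_vertex)) doc$watershed_vertex <- rois$watershed_vertex
  if (!is.null(rois$calibration_points))
    doc$calibration <- rois$calibration_points
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
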