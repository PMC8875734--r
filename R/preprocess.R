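#' Fit a flat-field illumination profile from a uniform-target recording
#'
#' The ring-light illumination of intra-operative NIR systems falls off
#' towards the image corners; left uncorrected this mimics reduced perfusion
#' there. The gain map is estimated as the temporal mean of a recording of a
#' spatially uniform fluorescent target, optionally Gaussian-blurred to
#' suppress target texture, and normalized to unit spatial mean.
#'
#' @param uniform_stack [frame_stack()] imaging a uniform target.
#' @param smoothing_sigma Gaussian blur sigma in pixels (0 disables; default
#'   5 px suppresses target texture without flattening the vignette).
#' @return An object of class `illumination_profile` with fields `gain`
#'   (height x width matrix, spatial mean 1) and `source`.
#' @export
fit_illumination_profile <- function(uniform_stack, smoothing_sigma = 5) {
  if (!inherits(uniform_stack, "frame_stack")) abort_input("uniform_stack must be a frame_stack")
  if (smoothing_sigma < 0) abort_input("smoothing_sigma must be >= 0")
  gain <- apply(uniform_stack$frames, c(2, 3), mean)
  if (smoothing_sigma > 0) gain <- EBImage::gblur(gain, sigma = smoothing_sigma)
  if (any(gain <= 0))
    abort_compute("degenerate illumination profile: non-positive mean pixel after blurring")
  gain <- gain / mean(gain)
  structure(list(gain = gain,
                 source = sprintf("temporal mean of %d uniform-target frames, blur sigma %g px",
                                  dim(uniform_stack$frames)[1], smoothing_sigma)),
            class = "illumination_profile")
}

#' Divide a recording by its illumination gain map
#'
#' @param stack A [frame_stack()].
#' @param profile An `illumination_profile` whose gain matches the frame shape.
#' @return A [frame_stack()] with floating-point, flat-fielded frames;
#'   frame rate unchanged.
#' @export
correct_illumination <- function(stack, profile) {
  d <- dim(stack$frames)
  if (!all(dim(profile$gain) == d[2:3]))
    abort_input("illumination profile dimensions do not match the frames")
  inv <- 1 / profile$gain
  frames <- stack$frames
  # sweep over the spatial dims of the [t, h, w] array
  frames <- frames * rep(inv, each = d[1])
  frame_stack(frames, stack$frame_rate, stack$t0_offset)
}

#' Remove a camera gain/exposure step from a trace
#'
#' When acquisition settings are adjusted mid-recording the signal jumps by
#' a multiplicative factor. Given the (user-annotated) change time, the
#' post-change segment is rescaled by the ratio of the mean raw intensity
#' over `reference_span` seconds immediately before versus immediately
#' after the change; pre-change samples are untouched.
#'
#' @param trace An [intensity_trace()] (raw series).
#' @param change_time Seconds; strictly inside the trace.
#' @param reference_span Seconds of signal on each side used for the ratio;
#'   at least 3 samples per side.
#' @return A corrected [intensity_trace()].
#' @export
normalize_gain_step <- function(trace, change_time, reference_span) {
  tm <- trace$time
  if (change_time <= tm[1] || change_time >= tm[length(tm)])
    abort_input("change_time must lie strictly inside the trace")
  stopifnot_scalar_pos(reference_span, "reference_span")
  pre <- tm >= change_time - reference_span & tm < change_time
  post <- tm >= change_time & tm < change_time + reference_span
  if (sum(pre) < 3L || sum(post) < 3L)
    abort_input("reference_span must contain at least 3 samples on each side")
  m_post <- mean(trace$raw[post])
  if (abs(m_post) < 1e-9)
    abort_compute("near-zero post-change reference mean; gain ratio undefined")
  ratio <- mean(trace$raw[pre]) / m_post
  raw <- trace$raw
  raw[tm >= change_time] <- raw[tm >= change_time] * ratio
  intensity_trace(trace$location_id, tm, raw)
}

#' Pixel-to-centimeter calibration from two ruler points
#'
#' A metric ruler in the field of view gives two annotated points a known
#' physical distance apart; the camera looks straight down from a fixed
#' height, so a single isotropic scale suffices.
#'
#' @param point_a,point_b Pixel coordinates `(row, col)`, 0-based.
#' @param physical_cm Physical separation of the points in cm.
#' @return An object of class `calibration` with field `pixels_per_cm` and
#'   the annotated provenance.
#' @export
calibrate_pixels <- function(point_a, point_b, physical_cm) {
  if (length(point_a) != 2L || length(point_b) != 2L)
    abort_input("calibration points must be (row, col) pairs")
  if (!is.numeric(physical_cm) || length(physical_cm) != 1L || physical_cm <= 0)
    abort_input("physical_cm must be a single positive number")
  d <- sqrt(sum((point_a - point_b)^2))
  if (d == 0) abort_input("calibration points must be distinct")
  structure(list(pixels_per_cm = d / physical_cm,
                 point_a = point_a, point_b = point_b, physical_cm = physical_cm),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %.4g px/cm\n", x$pixels_per_cm))
  invisible(x)
}

#' Write an illumination profile (32-bit TIFF + JSON sidecar)
#' @param profile An `illumination_profile`.
#' @param path Output TIFF path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_illumination_profile <- function(profile, path) {
  scale <- max(profile$gain)
  tiff::writeTIFF(profile$gain / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(list(gain_scale = scale, source = profile$source),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an illumination profile written by [write_illumination_profile()]
#' @param path TIFF path with its `<path>.json` sidecar.
#' @return An `illumination_profile`.
#' @export
read_illumination_profile <- function(path) {
  if (!file.exists(path)) abort_input("no such file: ", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) abort_input("illumination profile sidecar missing: ", sidecar)
  meta <- jsonlite::read_json(sidecar)
  gain <- tiff::readTIFF(path) * meta$gain_scale
  structure(list(gain = gain, source = meta$source %||% "file"),
            class = "illumination_profile")
}
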