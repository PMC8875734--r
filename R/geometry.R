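#' Geometry measures of the perfusion boundary
#'
#' @param demarcation_found `TRUE` when a perfusion demarcation proximal to
#'   the fundus tip was localized; `FALSE` when fluorescence reaches the tip.
#' @param demarcation_to_fundus_cm Arc distance from the demarcation to the
#'   fundus tip along the centerline (0 when not found).
#' @param watershed_to_fundus_cm Arc distance from the watershed annotation
#'   to the fundus tip.
#' @param centerline Optional n x 2 `(row, col)` polyline, base to tip.
#' @return An object of class `geometry_measures`.
#' @export
geometry_measures <- function(demarcation_found, demarcation_to_fundus_cm,
                              watershed_to_fundus_cm = NA_real_, centerline = NULL) {
  if (!is.na(demarcation_to_fundus_cm) && demarcation_to_fundus_cm < 0)
    abort_input("distances must be >= 0")
  structure(list(demarcation_found = demarcation_found,
                 demarcation_to_fundus_cm = demarcation_to_fundus_cm,
                 watershed_to_fundus_cm = watershed_to_fundus_cm,
                 centerline = centerline),
            class = "geometry_measures")
}

#' Arc length of a pixel polyline in centimeters
#'
#' Sum of Euclidean segment lengths divided by the calibration's
#' pixels-per-cm. Arc length along the (curved) conduit, not straight-line
#' displacement: a chord would systematically underestimate anatomical
#' distance.
#'
#' @param points n x 2 matrix of `(row, col)` pixel vertices, n >= 2.
#' @param calib A [calibrate_pixels()] result.
#' @return Length in cm.
#' @export
measure_polyline_cm <- function(points, calib) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) abort_input("a polyline needs at least 2 points")
  seg <- sqrt(rowSums(diff(points)^2))
  sum(seg) / calib$pixels_per_cm
}

# cumulative arc position (px) of each vertex
vertex_arcs <- function(points) {
  c(0, cumsum(sqrt(rowSums(diff(as.matrix(points))^2))))
}

# mean of image over a disc of radius r px around a 0-based (row,col) point,
# clipped to the frame
disc_mean <- function(image, center, radius = 5) {
  h <- nrow(image); w <- ncol(image)
  rows <- max(1, floor(center[1] + 1 - radius)):min(h, ceiling(center[1] + 1 + radius))
  cols <- max(1, floor(center[2] + 1 - radius)):min(w, ceiling(center[2] + 1 + radius))
  rr <- outer(rows - 1 - center[1], rep(1, length(cols)))
  cc <- outer(rep(1, length(rows)), cols - 1 - center[2])
  sel <- rr^2 + cc^2 <= radius^2
  mean(image[rows, cols][sel])
}

#' Localize the perfusion demarcation and measure its distance to the tip
#'
#' At the end of the recording ICG has accumulated in all perfused tissue,
#' so the late-phase image (temporal mean of the final seconds, flat-field
#' corrected) separates perfused from non-perfused conduit. The reference
#' level is the median late-phase intensity along the proximal third of the
#' centerline; walking the centerline from the tip backwards, the
#' demarcation is the most distal vertex whose local intensity (mean over a
#' 5 px disc) still reaches `threshold_fraction` of the reference. When the
#' tip itself is above threshold the conduit is perfused throughout and the
#' distance is zero.
#'
#' @param late_image 2-D intensity map (height x width).
#' @param centerline n x 2 `(row, col)` polyline ordered base to fundus tip.
#' @param calib A [calibrate_pixels()] result.
#' @param threshold_fraction Fraction of the proximal reference level
#'   (default 0.25) below which tissue counts as non-perfused. There is no
#'   canonical operational definition of the visible demarcation, so this
#'   is deliberately prominent and logged.
#' @param disc_radius_px Radius of the local sampling disc (default 5 px).
#' @return A [geometry_measures()] (watershed distance left `NA`).
#' @export
detect_demarcation <- function(late_image, centerline, calib,
                               threshold_fraction = 0.25, disc_radius_px = 5) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    abort_input("threshold_fraction must be in (0, 1)")
  centerline <- as.matrix(centerline)
  n <- nrow(centerline)
  if (n < 2L) abort_input("centerline needs at least 2 vertices")
  local <- vapply(seq_len(n),
                  function(i) disc_mean(late_image, centerline[i, ], disc_radius_px),
                  numeric(1))
  prox <- seq_len(max(2L, floor(n / 3)))
  ref <- median(local[prox])
  if (ref <= 0) abort_compute("degenerate late-phase image: proximal reference level <= 0")
  thr <- threshold_fraction * ref
  qualifying <- which(local >= thr)
  arcs <- vertex_arcs(centerline)
  if (length(qualifying) == 0L) {
    # nothing reaches threshold: report the whole centerline as distal
    return(geometry_measures(TRUE, arcs[n] / calib$pixels_per_cm,
                             centerline = centerline))
  }
  last_perf <- max(qualifying)
  if (last_perf == n)
    return(geometry_measures(FALSE, 0, centerline = centerline))
  dist_cm <- (arcs[n] - arcs[last_perf]) / calib$pixels_per_cm
  geometry_measures(TRUE, dist_cm, centerline = centerline)
}

#' Arc distance from the watershed annotation to the fundus tip
#'
#' The watershed (end of the supplying artery's territory, marked
#' intra-operatively with a gauze) is projected onto the nearest centerline
#' vertex; the result is the centerline arc length from there to the tip.
#'
#' @param watershed_point Pixel `(row, col)`, within 20 px of the centerline.
#' @param centerline n x 2 `(row, col)` polyline ordered base to fundus tip.
#' @param calib A [calibrate_pixels()] result.
#' @return Distance in cm.
#' @export
measure_watershed_distance <- function(watershed_point, centerline, calib) {
  centerline <- as.matrix(centerline)
  d2 <- (centerline[, 1] - watershed_point[1])^2 + (centerline[, 2] - watershed_point[2])^2
  i <- which.min(d2)
  if (sqrt(d2[i]) > 20)
    abort_input("watershed annotation is farther than 20 px from the centerline")
  arcs <- vertex_arcs(centerline)
  (arcs[length(arcs)] - arcs[i]) / calib$pixels_per_cm
}

#' Late-phase image of a recording
#'
#' Temporal mean of the final `window_s` seconds, the default input to
#' [detect_demarcation()].
#'
#' @param stack A [frame_stack()] (illumination-corrected).
#' @param window_s Seconds from the end of the recording (default 10).
#' @return Height x width intensity matrix.
#' @export
late_phase_image <- function(stack, window_s = 10) {
  tm <- frame_times(stack)
  sel <- tm >= tm[length(tm)] - window_s + 1e-9
  apply(stack$frames[sel, , , drop = FALSE], c(2, 3), mean)
}
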