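#' Build a fixed-area circular ROI mask
#'
#' An ROI is the set of exactly `area` pixels nearest its center by
#' Euclidean distance (the field's "circle of 300 pixels"), with distance
#' ties broken by ascending row, then column, which makes masks reproducible
#' across platforms. If the disc would extend past the frame border the
#' call fails rather than silently shrinking the ROI.
#'
#' @param center Pixel `(row, col)`, 0-based, inside the frame.
#' @param area Number of pixels in the mask (default 300).
#' @param frame_shape `(height, width)` in pixels.
#' @return Logical height x width matrix with exactly `area` `TRUE` pixels.
#' @export
build_roi_mask <- function(center, area = 300, frame_shape) {
  h <- frame_shape[1]; w <- frame_shape[2]
  if (area < 1 || area > h * w) abort_input("area must be in 1..height*width")
  if (center[1] < 0 || center[1] > h - 1 || center[2] < 0 || center[2] > w - 1)
    abort_input("ROI center lies outside the frame")
  sel <- roi_pixel_list(center, area, frame_shape)
  if (any(sel[, 1] < 0 | sel[, 1] > h - 1 | sel[, 2] < 0 | sel[, 2] > w - 1))
    abort_input("ROI of ", area, " pixels at (", center[1], ",", center[2],
                ") would be clipped by the frame border")
  mask <- matrix(FALSE, h, w)
  mask[cbind(sel[, 1] + 1, sel[, 2] + 1)] <- TRUE
  mask
}

# The `area` nearest lattice pixels to `center` (unbounded lattice), ordered
# by (distance^2, row, col); rows are 0-based (row, col) pairs.
roi_pixel_list <- function(center, area, frame_shape) {
  r <- 1
  repeat {
    rows <- (floor(center[1]) - r):(ceiling(center[1]) + r)
    cols <- (floor(center[2]) - r):(ceiling(center[2]) + r)
    grid <- expand.grid(row = rows, col = cols)
    d2 <- (grid$row - center[1])^2 + (grid$col - center[2])^2
    # only pixels strictly inside the inscribed radius are guaranteed
    # complete; enlarge the candidate square until `area` of them fit
    if (sum(d2 <= r^2) >= area) {
      ord <- order(d2, grid$row, grid$col)
      sel <- grid[ord[seq_len(area)], ]
      return(cbind(sel$row, sel$col))
    }
    r <- r + 2
  }
}

#' Extract per-location time-intensity traces from a recording
#'
#' For each ROI the raw trace is the arithmetic mean intensity over the
#' mask in every consecutive frame; the time base is the frame index over
#' the frame rate.
#'
#' @param stack A [frame_stack()].
#' @param rois A [roi_set()].
#' @return List of [intensity_trace()] in location order.
#' @export
extract_traces <- function(stack, rois) {
  if (!inherits(rois, "roi_set") || length(rois$rois) == 0L)
    abort_input("a non-empty roi_set is required")
  d <- dim(stack$frames)
  tm <- frame_times(stack)
  nt <- d[1]
  flat <- matrix(stack$frames, nrow = nt)  # [t, h*w]
  lapply(rois$rois, function(r) {
    mask <- build_roi_mask(r$center, r$area, d[2:3])
    raw <- rowMeans(flat[, as.vector(mask), drop = FALSE])
    intensity_trace(r$location, tm, raw)
  })
}
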