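#' Robust local-regression smoothing of a trace
#'
#' Each sample is replaced by the value at its own position of a
#' weighted-least-squares line fitted over a centered window of
#' `smoothing_span` samples (the window slides one-sidedly into the trace at
#' both ends, so it always holds the span nearest samples). Weights are
#' tricube in distance, multiplied by robust weights refined over
#' `robust_iterations` passes: residuals beyond `robust_cutoff` times the
#' robust residual scale get zero weight (bisquare inside the cutoff). With
#' the default `"mad"` scale the estimate is the median absolute residual,
#' which stays finite in the presence of the very outliers being rejected;
#' `"sd"` selects the plain residual standard deviation instead.
#'
#' Degree-1 local regression reproduces affine signals exactly, so smoothing
#' never biases a linear bolus rise.
#'
#' @param trace An [intensity_trace()] with a raw series at least as long as
#'   the span.
#' @param config A [quant_config()].
#' @return The trace with its `smoothed` series filled in; the raw series is
#'   unchanged. The number of windows that fell back to an unweighted fit
#'   (all-zero weights) is attached as attribute `fallback_windows`.
#' @export
smooth_trace <- function(trace, config = quant_config()) {
  y <- trace$raw
  n <- length(y)
  span <- config$smoothing_span
  if (n < span) abort_input("trace has ", n, " samples; smoothing span needs >= ", span)
  sm <- robust_local_linear(y, span, config$robust_cutoff, config$robust_iterations,
                            config$robust_scale)
  out <- intensity_trace(trace$location_id, trace$time, y, smoothed = sm$s,
                         derivative = trace$derivative)
  attr(out, "fallback_windows") <- sm$fallbacks
  out
}

robust_local_linear <- function(y, span, cutoff, iterations, scale_kind) {
  n <- length(y)
  h <- (span - 1L) %/% 2L
  ws <- pmin(pmax(seq_len(n) - h, 1L), n - span + 1L)
  robw <- rep(1, n)
  s <- numeric(n)
  fallbacks <- 0L
  offs <- 0:(span - 1L)
  for (pass in 0:iterations) {
    for (i in seq_len(n)) {
      idx <- ws[i] + offs
      d <- abs(idx - i)
      dmax <- max(d)
      w <- (1 - (d / dmax)^3)^3 * robw[idx]
      if (all(w <= 0)) {             # every sample rejected: plain fit
        w <- rep(1, span)
        if (pass == iterations) fallbacks <- fallbacks + 1L
      }
      x <- idx - i
      yy <- y[idx]
      sw <- sum(w); sx <- sum(w * x); sxx <- sum(w * x * x)
      sy <- sum(w * yy); sxy <- sum(w * x * yy)
      det <- sw * sxx - sx * sx
      fit <- if (det > 1e-300) (sxx * sy - sx * sxy) / det else sy / sw
      # a near-degenerate weight pattern (e.g. most of a window rejected)
      # can extrapolate; the local fit never needs to leave the window's
      # data range
      s[i] <- min(max(fit, min(yy)), max(yy))
    }
    if (pass == iterations) break
    r <- y - s
    scale <- if (scale_kind == "mad") median(abs(r)) else sd(r)
    # On noiseless smooth traces the residual scale collapses to the tiny
    # fit bias, and the cutoff would then reject whole curved regions.
    # Floor the scale at a small fraction of the signal range: far below
    # any genuine outlier, far above numerical fit bias.
    s_eff <- max(scale, 1e-4 * (diff(range(y)) + 1e-12))
    u <- abs(r) / (cutoff * s_eff)
    robw <- ifelse(u >= 1, 0, (1 - u^2)^2)
  }
  list(s = s, fallbacks = fallbacks)
}

#' Point-wise derivative of a smoothed trace
#'
#' Central differences at interior samples (exact for quadratics) and
#' one-sided differences at the two ends, in intensity per second.
#'
#' @param trace An [intensity_trace()] whose `smoothed` series is present
#'   (length >= 3).
#' @return The trace with its `derivative` series filled in.
#' @export
pointwise_derivative <- function(trace) {
  s <- trace$smoothed
  if (is.null(s)) abort_compute("smoothed series missing; run smooth_trace() first")
  n <- length(s)
  if (n < 3L) abort_input("derivative needs at least 3 samples")
  dt <- trace_dt(trace)
  d <- numeric(n)
  d[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) / (2 * dt)
  d[1] <- (s[2] - s[1]) / dt
  d[n] <- (s[n] - s[n - 1]) / dt
  intensity_trace(trace$location_id, trace$time, trace$raw, trace$smoothed, d)
}

#' Baseline noise statistics of the derivative
#'
#' Mean and sample standard deviation (n-1 denominator) of the point-wise
#' derivative over the pre-influx noise window (samples with
#' `time < noise_window`), the reference for the influx criterion.
#'
#' @param trace An [intensity_trace()] with its derivative present.
#' @param config A [quant_config()].
#' @return List of class `noise_stats`: `location_id`, `mu_noise`,
#'   `sigma_noise` (intensity/s) and `n_samples`.
#' @export
compute_noise_stats <- function(trace, config = quant_config()) {
  d <- trace$derivative
  if (is.null(d)) abort_compute("derivative missing; run pointwise_derivative() first")
  in_win <- trace$time < config$noise_window - 1e-9
  if (sum(in_win) < 2L) abort_input("noise window holds fewer than 2 samples")
  structure(list(location_id = trace$location_id,
                 mu_noise = mean(d[in_win]),
                 sigma_noise = sd(d[in_win]),
                 n_samples = sum(in_win)),
            class = "noise_stats")
}

#' Detect the influx timepoint tau
#'
#' The influx timepoint is the first sample, at or after the end of the
#' noise window, whose derivative exceeds
#' `mu_noise + influx_k * max(sigma_noise, sigma_floor)` and that starts a
#' run of `sustain_samples` consecutive supra-threshold samples. The sigma
#' floor (`sigma_floor_frac` of the trace's intensity range) keeps the
#' threshold meaningful when a noiseless baseline gives sigma_noise = 0.
#' The search starts only after the noise window, since the criterion is
#' undefined on the data that defined it.
#'
#' @param trace An [intensity_trace()] with its derivative present.
#' @param noise A `noise_stats` from [compute_noise_stats()].
#' @param config A [quant_config()].
#' @return Tau in seconds, or `NA` when no influx qualifies (a value, not
#'   an error).
#' @export
detect_influx <- function(trace, noise, config = quant_config()) {
  d <- trace$derivative
  if (is.null(d)) abort_compute("derivative missing; run pointwise_derivative() first")
  floor_sigma <- config$sigma_floor_frac * diff(range(trace$raw))
  thr <- noise$mu_noise + config$influx_k * max(noise$sigma_noise, floor_sigma)
  eligible <- trace$time >= config$noise_window - 1e-9
  above <- d > thr & eligible
  m <- config$sustain_samples
  n <- length(d)
  for (i in which(above)) {
    if (i + m - 1L <= n && all(above[i:(i + m - 1L)])) return(trace$time[i])
  }
  UNDETECTED
}

#' Mean slope F_slope over the post-influx window
#'
#' Arithmetic mean of the point-wise derivative over the half-open window
#' `[tau, tau + slope_window)`; flags truncation when the recording ends
#' before the window does.
#'
#' @param trace An [intensity_trace()] with its derivative present.
#' @param tau Detected influx timepoint in seconds.
#' @param config A [quant_config()].
#' @return Numeric F_slope (intensity/s) with attribute `window_truncated`.
#' @export
compute_fslope <- function(trace, tau, config = quant_config()) {
  d <- trace$derivative
  if (is.null(d)) abort_compute("derivative missing; run pointwise_derivative() first")
  if (is.na(tau)) abort_input("tau is undetected; F_slope undefined")
  in_win <- trace$time >= tau - 1e-9 & trace$time < tau + config$slope_window - 1e-9
  if (sum(in_win) < 2L) abort_input("fewer than 2 derivative samples in the F_slope window")
  out <- mean(d[in_win])
  attr(out, "window_truncated") <-
    trace$time[length(trace$time)] < tau + config$slope_window - 1e-9
  out
}

#' Maximal intensity F_max over the post-influx window
#'
#' Maximum of the smoothed (default) or raw series over the closed window
#' `[tau, tau + fmax_window]`, truncated at the last sample when the
#' recording is shorter (common: intra-operative recordings are capped at
#' 2-3 min and poorly perfused regions may not peak in time).
#'
#' @param trace An [intensity_trace()] with the configured series present.
#' @param tau Detected influx timepoint in seconds.
#' @param config A [quant_config()].
#' @return Numeric F_max with attribute `window_truncated`.
#' @export
compute_fmax <- function(trace, tau, config = quant_config()) {
  series <- if (config$fmax_series == "smoothed") trace$smoothed else trace$raw
  if (is.null(series)) abort_compute("smoothed series missing; run smooth_trace() first")
  if (is.na(tau)) abort_input("tau is undetected; F_max undefined")
  in_win <- trace$time >= tau - 1e-9 & trace$time <= tau + config$fmax_window + 1e-9
  if (!any(in_win)) abort_input("empty F_max window")
  out <- max(series[in_win])
  attr(out, "window_truncated") <-
    trace$time[length(trace$time)] < tau + config$fmax_window - 1e-9
  out
}

#' Quantify one trace: smoothing, derivative, influx, F_slope, F_max
#'
#' Runs the full per-location pipeline: [smooth_trace()] ->
#' [pointwise_derivative()] -> [compute_noise_stats()] -> [detect_influx()]
#' -> [compute_fslope()] / [compute_fmax()]. When no influx is detected the
#' result carries `NA` sentinels and `influx_detected = FALSE`.
#'
#' @param trace An [intensity_trace()] with a raw series.
#' @param config A [quant_config()].
#' @return A [perfusion_params()]; the processed trace (with smoothed and
#'   derivative series) is attached as attribute `trace`, the noise
#'   statistics as attribute `noise`.
#' @export
quantify_trace <- function(trace, config = quant_config()) {
  tr <- smooth_trace(trace, config)
  tr <- pointwise_derivative(tr)
  noise <- compute_noise_stats(tr, config)
  tau <- detect_influx(tr, noise, config)
  if (is.na(tau)) {
    out <- perfusion_params(trace$location_id)
  } else {
    fs <- compute_fslope(tr, tau, config)
    fm <- compute_fmax(tr, tau, config)
    out <- perfusion_params(trace$location_id, tau = tau,
                            f_max = as.numeric(fm), f_slope = as.numeric(fs),
                            influx_detected = TRUE,
                            window_truncated = attr(fs, "window_truncated") ||
                              attr(fm, "window_truncated"))
  }
  attr(out, "trace") <- tr
  attr(out, "noise") <- noise
  out
}
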