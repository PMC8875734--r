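# Independent oracles used across the suite. These deliberately take the
# slow, definitional route so they stay independent of the implementation.

# exhaustive ROI oracle: sort every pixel of the frame by (distance^2, row,
# col) and take the first `area`; returns 0-based (row, col) matrix
brute_force_roi <- function(center, area, frame_shape) {
  grid <- expand.grid(row = 0:(frame_shape[1] - 1), col = 0:(frame_shape[2] - 1))
  d2 <- (grid$row - center[1])^2 + (grid$col - center[2])^2
  ord <- order(d2, grid$row, grid$col)
  as.matrix(grid[ord[seq_len(area)], ])
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
enum_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# repeated-measures ANOVA by explicit cell-wise deviations (loops, no
# matrix shortcuts)
brute_force_rm_anova_f <- function(y) {
  n <- nrow(y); k <- ncol(y)
  grand <- sum(y) / (n * k)
  ss_cond <- 0
  for (j in seq_len(k)) ss_cond <- ss_cond + n * (mean(y[, j]) - grand)^2
  ss_err <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    ss_err <- ss_err + (y[i, j] - mean(y[i, ]) - mean(y[, j]) + grand)^2
  }
  (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
}

# first time the analytic model derivative sustainedly exceeds the
# threshold rule, scanned on a fine grid (influx-detection oracle)
brute_force_influx_scan <- function(loc, threshold, t_from, t_to, dt = 1e-3, sustain = 3) {
  tm <- seq(t_from, t_to, by = dt)
  dv <- (kinetic_model(tm + dt / 2, loc) - kinetic_model(tm - dt / 2, loc)) / dt
  above <- dv > threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  for (i in seq_along(runs$lengths)) {
    if (runs$values[i] && runs$lengths[i] >= sustain)
      return(tm[ends[i] - runs$lengths[i] + 1])
  }
  NA_real_
}

# convenience: noiseless trace builders on a uniform time base
make_trace <- function(values, frame_rate = 25, location = 1L) {
  tm <- (seq_along(values) - 1) / frame_rate
  intensity_trace(location, tm, values)
}

affine_trace <- function(n = 600, a = 5, b = 2, frame_rate = 25) {
  tm <- (seq_len(n) - 1) / frame_rate
  intensity_trace(1L, tm, a + b * tm)
}

# tiny phantom spec for IO/pipeline tests (keeps files and runtimes small)
small_phantom_spec <- function(seed = 1L) {
  phantom_spec(
    kinetics = kinetic_spec(frame_rate = 5, duration = 40, noise_sigma = 1, seed = seed),
    image_size = c(72L, 112L), pixels_per_cm = 8, conduit_halfwidth_px = 8,
    roi_arc_from_tip_cm = c(10.5, 7.5, 4.5, 3.0), demarcation_cm = 2.0,
    roi_area = 60, uniform_frames = 10L)
}
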