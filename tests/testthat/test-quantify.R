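test_that("smoothing leaves constants and affine traces untouched", {
  const <- make_trace(rep(100, 200))
  expect_equal(smooth_trace(const)$smoothed, rep(100, 200), tolerance = 1e-12)

  aff <- affine_trace(n = 300)
  sm <- smooth_trace(aff)
  expect_lt(max(abs(sm$smoothed - aff$raw)), 1e-9)   # ends included

  expect_error(smooth_trace(make_trace(rep(1, 10))), class = "icgquant_input_error")
})

test_that("robust reweighting zero-weights an injected spike", {
  aff <- affine_trace(n = 600)
  spiked <- aff$raw
  spiked[300] <- spiked[300] + 100
  sm <- smooth_trace(intensity_trace(1L, aff$time, spiked))
  clean <- smooth_trace(aff)
  # the spike sample itself is pulled back onto the affine line
  expect_lt(abs(sm$smoothed[300] - aff$raw[300]), 1e-6)
  # samples outside the spike's windows are untouched
  away <- c(1:280, 320:600)
  expect_lt(max(abs(sm$smoothed[away] - clean$smoothed[away])), 1e-6)
})

test_that("point-wise derivatives are exact for quadratics and bounded for sin", {
  tm <- seq(0, 20, by = 0.1)
  tr <- intensity_trace(1L, tm, tm, smoothed = tm^2)
  dv <- pointwise_derivative(tr)$derivative
  interior <- 2:(length(tm) - 1)
  expect_equal(dv[interior], 2 * tm[interior], tolerance = 1e-9)

  tm <- seq(0, 6, by = 0.01)
  tr <- intensity_trace(1L, tm, tm, smoothed = sin(tm) + 2)
  dv <- pointwise_derivative(tr)$derivative
  expect_lt(max(abs(dv[2:(length(tm) - 1)] - cos(tm[2:(length(tm) - 1)]))),
            0.01^2 / 6 + 1e-9)

  flat <- intensity_trace(1L, tm, tm, smoothed = rep(5, length(tm)))
  expect_equal(pointwise_derivative(flat)$derivative, rep(0, length(tm)))

  expect_error(pointwise_derivative(make_trace(1:50)), class = "icgquant_compute_error")
})

test_that("noise statistics use the first seconds of the derivative", {
  tm <- (0:2) * 2
  tr <- intensity_trace(1L, tm, tm, smoothed = tm, derivative = c(-1, 0, 1))
  ns <- compute_noise_stats(tr, quant_config(noise_window = 10))
  expect_equal(ns$mu_noise, 0)
  expect_equal(ns$sigma_noise, 1)
  expect_identical(ns$n_samples, 3L)

  # 25 Hz, 10 s window: exactly 250 samples
  tm <- (0:999) / 25
  tr <- intensity_trace(1L, tm, tm, smoothed = tm, derivative = rep(0, 1000))
  expect_identical(compute_noise_stats(tr)$n_samples, 250L)

  short <- intensity_trace(1L, c(0, 20, 40), c(1, 1, 1), smoothed = c(1, 1, 1),
                           derivative = c(0, 0, 0))
  expect_error(compute_noise_stats(short, quant_config(noise_window = 10)),
               class = "icgquant_input_error")
})

test_that("influx detection translates the threshold crossing into tau", {
  # flat noiseless trace: nothing to detect
  flat <- quantify_trace(make_trace(rep(10, 500)))
  expect_false(flat$influx_detected)
  expect_true(is.na(flat$tau))

  # derivative exceeding the threshold from 0-based sample 300 of a 25 Hz
  # trace: tau = 12.0 s
  n <- 1000
  tm <- (0:(n - 1)) / 25
  dv <- rep(0, n)
  dv[301:n] <- 1
  tr <- intensity_trace(1L, tm, raw = c(rep(0, 300), cumsum(dv[301:n]) / 25),
                        smoothed = rep(0, n), derivative = dv)
  ns <- compute_noise_stats(tr)
  expect_equal(detect_influx(tr, ns), 12.0)

  # sustain guard: a single-sample excursion is ignored at the default
  # sustain of 3, found at sustain 1
  dv2 <- rep(0, n); dv2[401] <- 1
  tr2 <- intensity_trace(1L, tm, raw = tm / max(tm), smoothed = rep(0, n),
                         derivative = dv2)
  ns2 <- compute_noise_stats(tr2)
  expect_true(is.na(detect_influx(tr2, ns2)))
  expect_equal(detect_influx(tr2, ns2, quant_config(sustain_samples = 1)), 16.0)
})

test_that("noiseless onset detection agrees with the analytic threshold scan", {
  loc <- list(location = 1L, baseline = 10, onset = 15, amplitude = 50,
              rise = 10, clearance = 0)   # initial slope 5 intensity/s
  spec <- kinetic_spec(locations = list(loc), noise_sigma = 0, frame_rate = 25,
                       duration = 80)
  tr <- generate_trace(spec, 1L)
  p <- quantify_trace(tr)
  ns <- attr(p, "noise")
  thr <- ns$mu_noise + 5.5 * max(ns$sigma_noise, 1e-6 * diff(range(tr$raw)))
  oracle <- brute_force_influx_scan(loc, thr, t_from = 10, t_to = 30)
  dt <- 1 / 25
  h <- (quant_config()$smoothing_span - 1) / 2
  expect_true(p$influx_detected)
  # detection on the smoothed derivative can lead or lag the analytic
  # crossing by at most the half-span smear, never more
  expect_gte(p$tau, oracle - (h + 2) * dt)
  expect_lte(p$tau, oracle + 10 * dt)
})

test_that("F_slope averages the derivative over [tau, tau + 10 s)", {
  n <- 1500
  tm <- (0:(n - 1)) / 25
  # indicator derivative: 1 exactly on the half-open window [20, 30)
  dv <- as.numeric(tm >= 20 & tm < 30)
  tr <- intensity_trace(1L, tm, raw = tm, smoothed = tm, derivative = dv)
  fs <- compute_fslope(tr, tau = 20)
  expect_equal(as.numeric(fs), 1)           # samples 500..749 only
  expect_false(attr(fs, "window_truncated"))

  dv0 <- rep(0, n)
  tr0 <- intensity_trace(1L, tm, raw = tm, smoothed = tm, derivative = dv0)
  expect_equal(as.numeric(compute_fslope(tr0, tau = 20)), 0)

  # affine rise at 3 intensity/s
  tr3 <- intensity_trace(1L, tm, raw = tm, smoothed = tm, derivative = rep(3, n))
  expect_equal(as.numeric(compute_fslope(tr3, tau = 20)), 3, tolerance = 1e-6)

  # recording ending inside the window flags truncation
  fs_tr <- compute_fslope(tr3, tau = 55)
  expect_true(attr(fs_tr, "window_truncated"))
})

test_that("F_max searches [tau, tau + 50 s] and flags truncation", {
  n <- 1500
  tm <- (0:(n - 1)) / 25
  sm <- tm   # monotone increasing
  tr <- intensity_trace(1L, tm, raw = sm, smoothed = sm)
  fm <- compute_fmax(tr, tau = 10)
  expect_equal(as.numeric(fm), sm[n])       # window truncated at 60 s
  expect_true(attr(fm, "window_truncated"))

  # peak inside the window: value taken at the peak, not the edges
  tm2 <- (0:1599) / 25   # long enough that [10, 60] fits the recording
  sm2 <- 100 - (tm2 - 30)^2
  tr2 <- intensity_trace(1L, tm2, raw = sm2, smoothed = sm2)
  fm2 <- compute_fmax(tr2, tau = 10)
  expect_equal(as.numeric(fm2), 100)
  expect_false(attr(fm2, "window_truncated"))
})

test_that("a noiseless washout bolus recovers its analytic peak value", {
  loc <- list(location = 1L, baseline = 10, onset = 12, amplitude = 120,
              rise = 1.5, clearance = 0.05)
  spec <- kinetic_spec(locations = list(loc), noise_sigma = 0, frame_rate = 25,
                       duration = 80)
  tr <- generate_trace(spec, 1L)
  truth <- attr(tr, "truth")
  # analytic peak lies inside the F_max window
  expect_lt(truth$peak_time, 12 + 50)
  p <- quantify_trace(tr, quant_config(fmax_series = "raw"))
  expect_equal(p$f_max, truth$window_max, tolerance = 1e-3)
})

test_that("quantification is scale- and shift-equivariant and delay-covariant", {
  loc <- list(location = 1L, baseline = 10, onset = 15, amplitude = 90,
              rise = 1.5, clearance = 0.01)
  spec <- kinetic_spec(locations = list(loc), noise_sigma = 0, frame_rate = 25,
                       duration = 80)
  tr <- generate_trace(spec, 1L)
  p <- quantify_trace(tr)
  expect_true(p$influx_detected)
  # degenerate-sigma guard: tau never lands inside the flat baseline
  expect_gte(p$tau, 15 - 2 / 25)

  cs <- 3.7
  p_scaled <- quantify_trace(intensity_trace(1L, tr$time, cs * tr$raw))
  expect_equal(p_scaled$tau, p$tau)
  expect_equal(p_scaled$f_max, cs * p$f_max, tolerance = 1e-6)
  expect_equal(p_scaled$f_slope, cs * p$f_slope, tolerance = 1e-6)

  b <- 25
  p_shift <- quantify_trace(intensity_trace(1L, tr$time, tr$raw + b))
  expect_equal(p_shift$tau, p$tau)
  expect_equal(p_shift$f_max, p$f_max + b, tolerance = 1e-6)
  expect_equal(p_shift$f_slope, p$f_slope, tolerance = 1e-6)

  d <- 2
  loc_d <- loc; loc_d$onset <- loc$onset + d
  tr_d <- generate_trace(kinetic_spec(locations = list(loc_d), noise_sigma = 0,
                                      frame_rate = 25, duration = 80), 1L)
  p_delay <- quantify_trace(tr_d)
  expect_equal(p_delay$tau - p$tau, d, tolerance = 1 / 25 + 1e-9)
  expect_equal(p_delay$f_max, p$f_max, tolerance = 1e-6)
  expect_equal(p_delay$f_slope, p$f_slope, tolerance = 1e-6)
})

test_that("synthetic base and fundus presets reproduce the clinical ordering", {
  spec <- kinetic_spec()
  p1 <- quantify_trace(generate_trace(spec, 1L))
  p4 <- quantify_trace(generate_trace(spec, 4L))
  expect_true(p1$influx_detected && p4$influx_detected)
  expect_gt(p4$tau, p1$tau)
  expect_lt(p4$f_max, p1$f_max)
  expect_lt(p4$f_slope, p1$f_slope)
})
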