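#' Kinetic specification for synthetic ICG traces
#'
#' The synthetic bolus model is an uptake-times-decay curve per location:
#' baseline `B` before onset `t0`, then
#' `B + A * (1 - exp(-(t - t0)/r)) * exp(-k * (t - t0))`.
#' It is the simplest form producing both observed regimes: arterial
#' locations rise fast and wash out (`k > 0`), while the fundus rises late
#' and weakly and keeps accumulating because venous ligation suppresses
#' clearance (`k = 0`). The default presets emulate a conduit whose base
#' fills early and strongly (onset 12 s, amplitude 120) and whose fundus
#' fills late and weakly (onset 20 s, amplitude 45, no clearance), over an
#' 8-bit intensity range with additive Gaussian sensor noise.
#'
#' @param locations List of per-location parameter lists with fields
#'   `location`, `label`, `baseline`, `onset` (s), `amplitude`, `rise` (s),
#'   `clearance` (1/s).
#' @param noise_sigma Additive Gaussian sigma in intensity units.
#' @param frame_rate Hz.
#' @param duration Seconds.
#' @param seed Integer seed; all generated randomness derives from it.
#' @return An object of class `kinetic_spec`.
#' @export
kinetic_spec <- function(locations = default_locations(), noise_sigma = 2,
                         frame_rate = 25, duration = 80, seed = 1L) {
  for (l in locations) {
    if (l$baseline < 0 || l$amplitude < 0) abort_input("baseline and amplitude must be >= 0")
    if (l$rise <= 0) abort_input("rise must be > 0 (location ", l$location, ")")
    if (l$clearance < 0) abort_input("clearance must be >= 0 (location ", l$location, ")")
    if (duration <= l$onset)
      abort_input("duration must exceed the onset of location ", l$location)
  }
  if (noise_sigma < 0) abort_input("noise_sigma must be >= 0")
  stopifnot_scalar_pos(frame_rate, "frame_rate")
  structure(list(locations = locations, noise_sigma = noise_sigma,
                 frame_rate = frame_rate, duration = duration,
                 seed = as.integer(seed)),
            class = "kinetic_spec")
}

#' @rdname kinetic_spec
#' @export
default_locations <- function() {
  list(
    list(location = 1L, label = "below_watershed", baseline = 10, onset = 12,
         amplitude = 120, rise = 1.5, clearance = 0.010),
    list(location = 2L, label = "watershed", baseline = 10, onset = 13,
         amplitude = 115, rise = 1.5, clearance = 0.010),
    list(location = 3L, label = "above_watershed", baseline = 10, onset = 15,
         amplitude = 100, rise = 2.0, clearance = 0.008),
    list(location = 4L, label = "fundus", baseline = 10, onset = 20,
         amplitude = 45, rise = 2.0, clearance = 0)
  )
}

#' Evaluate the synthetic bolus model
#'
#' Continuous at the onset, equal to the baseline before it, non-negative
#' everywhere. With no clearance the curve saturates at `B + A`
#' (accumulation plateau); with clearance it peaks at
#' `t0 + r * log(1 + 1/(k*r))` and decays.
#'
#' @param t Time(s) in seconds (vectorized).
#' @param loc A per-location parameter list (see [kinetic_spec()]).
#' @return Intensity value(s).
#' @export
kinetic_model <- function(t, loc) {
  dt <- t - loc$onset
  ifelse(dt < 0, loc$baseline,
         loc$baseline + loc$amplitude * (1 - exp(-dt / loc$rise)) * exp(-loc$clearance * dt))
}

# closed-form max of the model over [t0, t0 + window]
kinetic_peak <- function(loc, window) {
  if (loc$clearance == 0) {
    t_peak <- loc$onset + window
  } else {
    t_star <- loc$onset + loc$rise * log(1 + 1 / (loc$clearance * loc$rise))
    t_peak <- min(t_star, loc$onset + window)
  }
  list(time = t_peak, value = kinetic_model(t_peak, loc))
}

# analytic mean derivative over [t0, t0 + window]
kinetic_window_slope <- function(loc, window) {
  (kinetic_model(loc$onset + window, loc) - kinetic_model(loc$onset, loc)) / window
}

#' Generate one synthetic trace with ground truth
#'
#' Samples the kinetic model on the spec's time base, adds seeded Gaussian
#' noise (clipped at zero) and stores the analytic ground truth used by
#' recovery tests: the onset, the analytic mean derivative over the 10 s
#' following onset, and the analytic maximum over the 50 s following onset.
#'
#' @param spec A [kinetic_spec()].
#' @param location_id Which location to generate.
#' @param slope_window,fmax_window Windows (s) for the stored ground truth.
#' @return An [intensity_trace()]; ground truth attached as attribute
#'   `truth` (fields `onset`, `window_slope`, `window_max`, `peak_time`,
#'   `baseline`, `amplitude`).
#' @export
generate_trace <- function(spec, location_id, slope_window = 10, fmax_window = 50) {
  loc <- spec_location(spec, location_id)
  tm <- seq(0, spec$duration - 1 / spec$frame_rate, by = 1 / spec$frame_rate)
  clean <- kinetic_model(tm, loc)
  raw <- if (spec$noise_sigma > 0) {
    withr::with_seed(spec$seed * 101L + loc$location, {
      pmax(clean + rnorm(length(tm), 0, spec$noise_sigma), 0)
    })
  } else clean
  tr <- intensity_trace(loc$location, tm, raw)
  attr(tr, "truth") <- list(
    onset = loc$onset,
    window_slope = kinetic_window_slope(loc, slope_window),
    window_max = kinetic_peak(loc, fmax_window)$value,
    peak_time = kinetic_peak(loc, fmax_window)$time,
    baseline = loc$baseline, amplitude = loc$amplitude)
  tr
}

spec_location <- function(spec, location_id) {
  for (l in spec$locations) if (l$location == location_id) return(l)
  abort_input("no location ", location_id, " in the kinetic spec")
}

#' Phantom scene specification
#'
#' Describes a synthetic conduit scene: a curved centerline from base to
#' fundus tip, location kinetics anchored at four arc positions, a
#' perfusion demarcation a known arc distance from the tip (pixels beyond
#' it keep baseline-only kinetics), a radially symmetric vignette emulating
#' ring-light illumination falloff, and a metric calibration.
#'
#' @param kinetics A [kinetic_spec()] (its `frame_rate`, `duration`,
#'   `noise_sigma` and `seed` drive the rendering).
#' @param image_size `(height, width)` in pixels.
#' @param pixels_per_cm Scene scale.
#' @param conduit_halfwidth_px Half-width of the rendered conduit.
#' @param roi_arc_from_tip_cm Arc positions of the four ROI centers,
#'   measured from the fundus tip (locations 1..4). The fundus ROI sits
#'   just proximal of any demarcated tip so that fundus kinetics remain
#'   measurable, as in recordings where a demarcation is visible distal to
#'   the measurement site.
#' @param watershed_arc_from_tip_cm Arc position of the watershed gauze.
#' @param demarcation_cm Arc distance of the perfusion boundary from the
#'   tip; 0 renders a conduit perfused to the tip.
#' @param vignette_strength Relative corner falloff of the illumination
#'   field (0 disables).
#' @param background Intensity of non-conduit pixels.
#' @param roi_area ROI size in pixels.
#' @param uniform_frames Frames of the uniform-target recording emitted for
#'   flat-field estimation.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kinetics = kinetic_spec(duration = 60),
                         image_size = c(140L, 225L),
                         pixels_per_cm = 16, conduit_halfwidth_px = 14,
                         roi_arc_from_tip_cm = c(10.5, 7.5, 4.5, 3.0),
                         watershed_arc_from_tip_cm = 7.5,
                         demarcation_cm = 2.0, vignette_strength = 0.3,
                         background = 2, roi_area = 300, uniform_frames = 50L) {
  if (demarcation_cm < 0) abort_input("demarcation_cm must be >= 0")
  if (vignette_strength < 0 || vignette_strength >= 1)
    abort_input("vignette_strength must be in [0, 1)")
  if (length(roi_arc_from_tip_cm) != 4L)
    abort_input("roi_arc_from_tip_cm needs one arc per location 1..4")
  structure(list(kinetics = kinetics, image_size = as.integer(image_size),
                 pixels_per_cm = pixels_per_cm,
                 conduit_halfwidth_px = conduit_halfwidth_px,
                 roi_arc_from_tip_cm = roi_arc_from_tip_cm,
                 watershed_arc_from_tip_cm = watershed_arc_from_tip_cm,
                 demarcation_cm = demarcation_cm,
                 vignette_strength = vignette_strength,
                 background = background, roi_area = roi_area,
                 uniform_frames = as.integer(uniform_frames)),
            class = "phantom_spec")
}

# default conduit centerline: a gentle sweep across the frame, resampled to
# ~1 px vertex spacing; 0-based (row, col) coordinates
default_centerline <- function(image_size) {
  h <- image_size[1]; w <- image_size[2]
  t <- seq(0, 1, length.out = 2000)
  rows <- 0.25 * h + 0.393 * h * t + 0.129 * h * sin(pi * t)
  cols <- 0.089 * w + 0.822 * w * t
  arcs <- c(0, cumsum(sqrt(diff(rows)^2 + diff(cols)^2)))
  total <- arcs[length(arcs)]
  s <- seq(0, total, by = 1)
  cbind(row = approx(arcs, rows, s)$y, col = approx(arcs, cols, s)$y)
}

radial_vignette <- function(image_size, strength) {
  h <- image_size[1]; w <- image_size[2]
  rr <- outer((seq_len(h) - (h + 1) / 2), rep(1, w))
  cc <- outer(rep(1, h), (seq_len(w) - (w + 1) / 2))
  d2 <- rr^2 + cc^2
  v <- 1 - strength * d2 / max(d2)
  v / mean(v)
}

#' Render a synthetic phantom recording with full ground truth
#'
#' Every conduit pixel's temporal profile follows the location kinetics
#' linearly interpolated by its arc position along the centerline; pixels
#' within `demarcation_cm` of the tip carry baseline-only kinetics. Frames
#' are multiplied by the vignette, perturbed with seeded Gaussian noise and
#' quantized to 8-bit. Alongside the stack the generator emits the scene
#' annotations (ROIs, centerline, watershed vertex, calibration points) and
#' a bookkeeping ground truth: the per-ROI per-frame means of the rendered
#' frames, per-ROI kinetic parameters and analytic window slope/max, the
#' true demarcation and watershed distances, and the per-ROI mean vignette
#' gain.
#'
#' @param spec A [phantom_spec()].
#' @return List with `stack` ([frame_stack()]), `uniform_stack` (uniform
#'   target for flat-field fitting), `annotations` ([roi_set()]), `truth`
#'   (list), `vignette` (matrix) and `spec`.
#' @export
generate_phantom_stack <- function(spec) {
  kin <- spec$kinetics
  h <- spec$image_size[1]; w <- spec$image_size[2]
  ppcm <- spec$pixels_per_cm
  cl <- default_centerline(spec$image_size)
  arcs <- vertex_arcs(cl)
  total_px <- arcs[length(arcs)]
  total_cm <- total_px / ppcm
  if (spec$demarcation_cm > total_cm)
    abort_input("demarcation_cm exceeds the centerline length (", round(total_cm, 1), " cm)")
  if (max(spec$roi_arc_from_tip_cm) > total_cm - 0.5)
    abort_input("ROI arcs fall off the proximal end of the centerline")

  # nearest centerline vertex (and hence arc position) for every pixel
  pr <- rep(seq_len(h) - 1, times = w)
  pc <- rep(seq_len(w) - 1, each = h)
  nearest <- nearest_vertex(pr, pc, cl)
  in_conduit <- nearest$dist <= spec$conduit_halfwidth_px
  arc_cm <- arcs[nearest$index[in_conduit]] / ppcm
  arc_to_tip <- total_cm - arc_cm

  # per-pixel kinetic parameters: piecewise-linear in arc position, with a
  # plateau around each location anchor wider than the ROI radius so each
  # ROI samples exactly its location's kinetics, and linear ramps between
  anchor_arc <- total_cm - spec$roi_arc_from_tip_cm   # cm from base, loc 1..4
  plateau <- 0.7                                      # cm half-width
  node_arc <- as.vector(rbind(anchor_arc - plateau, anchor_arc + plateau))
  if (any(diff(node_arc) <= 0))
    abort_input("ROI anchor arcs too close: kinetic plateaus overlap")
  par_of <- function(field) {
    v <- vapply(kin$locations, function(l) l[[field]], numeric(1))
    approx(node_arc, rep(v, each = 2), arc_cm, rule = 2)$y
  }
  px <- list(baseline = par_of("baseline"), onset = par_of("onset"),
             amplitude = par_of("amplitude"), rise = par_of("rise"),
             clearance = par_of("clearance"))
  px$amplitude[arc_to_tip < spec$demarcation_cm] <- 0   # non-perfused tip

  vig <- if (spec$vignette_strength > 0)
    radial_vignette(spec$image_size, spec$vignette_strength) else matrix(1, h, w)
  tm <- seq(0, kin$duration - 1 / kin$frame_rate, by = 1 / kin$frame_rate)
  nt <- length(tm)
  conduit_idx <- which(in_conduit)

  frames <- array(0L, dim = c(nt, h, w))
  base_frame <- matrix(spec$background, h, w)
  vig_vec <- as.vector(vig)
  withr::with_seed(kin$seed * 211L + 1L, {
    for (i in seq_len(nt)) {
      dt <- tm[i] - px$onset
      vals <- ifelse(dt < 0, px$baseline,
                     px$baseline + px$amplitude * (1 - exp(-pmax(dt, 0) / px$rise)) *
                       exp(-px$clearance * pmax(dt, 0)))
      fr <- base_frame
      fr[conduit_idx] <- vals
      fr <- as.vector(fr) * vig_vec
      if (kin$noise_sigma > 0) fr <- fr + rnorm(h * w, 0, kin$noise_sigma)
      frames[i, , ] <- as.integer(pmin(pmax(round(fr), 0), 255))
    }
  })
  stack <- frame_stack(frames, kin$frame_rate)

  uniform <- array(0L, dim = c(spec$uniform_frames, h, w))
  withr::with_seed(kin$seed * 211L + 2L, {
    for (i in seq_len(spec$uniform_frames)) {
      fr <- 100 * vig_vec + rnorm(h * w, 0, kin$noise_sigma)
      uniform[i, , ] <- as.integer(pmin(pmax(round(fr), 0), 255))
    }
  })
  uniform_stack <- frame_stack(uniform, kin$frame_rate)

  # annotations: ROIs at the anchor vertices, calibration 2 cm apart
  roi_vertex <- vapply(anchor_arc, function(a) which.min(abs(arcs / ppcm - a)), integer(1))
  rois <- lapply(1:4, function(l) {
    list(location = l, label = kin$locations[[l]]$label,
         center = unname(cl[roi_vertex[l], ]), area = spec$roi_area)
  })
  ws_vertex <- which.min(abs(arcs / ppcm - (total_cm - spec$watershed_arc_from_tip_cm)))
  calib_px <- round(2 * ppcm)
  ann <- roi_set(rois, centerline = cl, watershed_vertex = ws_vertex - 1L,
                 calibration_points = list(point_a = c(5, 10),
                                           point_b = c(5, 10 + calib_px),
                                           physical_cm = calib_px / ppcm))

  masks <- lapply(rois, function(r) build_roi_mask(r$center, r$area, c(h, w)))
  flat <- matrix(frames, nrow = nt)
  roi_means <- lapply(masks, function(m) rowMeans(flat[, as.vector(m), drop = FALSE]))
  loc_truth <- lapply(1:4, function(l) {
    loc <- kin$locations[[l]]
    list(location = l, onset = loc$onset,
         window_slope = kinetic_window_slope(loc, 10),
         window_max = kinetic_peak(loc, 50)$value,
         mean_gain = mean(vig[masks[[l]]]))
  })
  truth <- list(demarcation_cm = spec$demarcation_cm,
                watershed_cm = (arcs[length(arcs)] - arcs[ws_vertex]) / ppcm,
                centerline_cm = total_cm,
                roi_frame_means = roi_means,
                locations = loc_truth)
  list(stack = stack, uniform_stack = uniform_stack, annotations = ann,
       truth = truth, vignette = vig, spec = spec)
}

nearest_vertex <- function(pr, pc, cl) {
  # block over pixels to bound the distance-matrix memory
  n <- length(pr)
  idx <- integer(n); dist <- numeric(n)
  block <- 20000L
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    d2 <- outer(pr[s:e], cl[, 1], "-")^2 + outer(pc[s:e], cl[, 2], "-")^2
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    dist[s:e] <- sqrt(d2[cbind(seq_len(e - s + 1L), j)])
  }
  list(index = idx, dist = dist)
}

#' Generate a synthetic patient cohort table
#'
#' Draws per-patient perfusion parameters from truncated-at-zero normal
#' distributions with configurable per-location means/SDs (defaults match
#' the observed group means of F_max: 129/129/123 at the three proximal
#' locations versus 51 at the fundus) and equicorrelated within-patient
#' structure. Patients labeled as leakage cases draw their fundus slope
#' from a distribution bounded above by 0.2 intensity/s and larger
#' demarcation distances, mirroring the observed leakage phenotype;
#' non-leakage fundus slopes are bounded below away from 0.2, so the risk
#' rule's construction guarantee holds at any noise level.
#'
#' @param n_patients Number of patients (>= 4).
#' @param leakage_fraction Fraction labeled as leakage (default 0.15,
#'   i.e. 3 of 20).
#' @param fmax_mean,fmax_sd Length-4 vectors per location.
#' @param tau_mean,tau_sd Length-4 vectors per location (s).
#' @param rho Within-patient equicorrelation across locations.
#' @param missing_loc1_fraction Fraction of patients whose location 1 is
#'   `NA` (conduit base intra-thoracic).
#' @param seed Integer seed.
#' @return Data frame in the [read_cohort_csv()] schema.
#' @export
generate_cohort <- function(n_patients = 20L, leakage_fraction = 0.15,
                            fmax_mean = c(129, 129, 123, 51),
                            fmax_sd = c(49, 56, 64, 39),
                            tau_mean = c(12, 13, 15, 22),
                            tau_sd = c(3, 3, 4, 6),
                            rho = 0.5, missing_loc1_fraction = 0, seed = 1L) {
  if (n_patients < 4L) abort_input("n_patients must be >= 4")
  if (leakage_fraction < 0 || leakage_fraction >= 1)
    abort_input("leakage_fraction must be in [0, 1)")
  if (any(fmax_sd <= 0) || any(tau_sd <= 0)) abort_input("SDs must be positive")
  n <- as.integer(n_patients)
  withr::with_seed(as.integer(seed) * 307L, {
    n_leak <- round(n * leakage_fraction)
    leak <- rep(FALSE, n)
    if (n_leak > 0) leak[sample.int(n, n_leak)] <- TRUE

    corr_draw <- function(mu, sd) {
      sigma <- diag(sd) %*% (matrix(rho, 4, 4) + diag(1 - rho, 4)) %*% diag(sd)
      z <- matrix(rnorm(n * 4), n, 4)
      sweep(z %*% chol(sigma), 2, mu, "+")
    }
    fmax <- pmax(corr_draw(fmax_mean, fmax_sd), 0)
    tau <- pmax(corr_draw(tau_mean, tau_sd), 10.5)
    fs123 <- pmax(corr_draw(c(2.5, 2.4, 2.0, 1.0), c(1, 1, 0.9, 0.5))[, 1:3], 0.3)
    fs4 <- ifelse(leak, stats::runif(n, 0.02, 0.18), pmax(rnorm(n, 1.0, 0.5), 0.25))
    demarc <- ifelse(leak, pmax(rnorm(n, 4.5, 1.2), 2), pmax(rnorm(n, 0.8, 0.8), 0))
    ws <- pmax(rnorm(n, 7, 1.5), 4)
    hemo <- list(MAP = c(71, 9), HR = c(85, 14), SBP = c(106, 17), DBP = c(65, 16),
                 CO = c(6.9, 2.3), SV = c(75.4, 18.5), SVV = c(7.8, 2.6), CI = c(3.1, 0.9))
    df <- data.frame(patient_id = seq_len(n), leakage = leak)
    for (l in 1:4) df[[paste0("f_max_loc", l)]] <- fmax[, l]
    for (l in 1:3) df[[paste0("f_slope_loc", l)]] <- fs123[, l]
    df$f_slope_loc4 <- fs4
    for (l in 1:4) df[[paste0("tau_loc", l)]] <- tau[, l]
    df$demarcation_cm <- demarc
    df$watershed_cm <- ws
    for (nm in names(hemo)) df[[nm]] <- pmax(rnorm(n, hemo[[nm]][1], hemo[[nm]][2]),
                                             0.1 * hemo[[nm]][1])
    if (missing_loc1_fraction > 0) {
      drop <- sample.int(n, round(n * missing_loc1_fraction))
      df$f_max_loc1[drop] <- NA
      df$f_slope_loc1[drop] <- NA
      df$tau_loc1[drop] <- NA
    }
    df[c("patient_id", "leakage",
         paste0("f_max_loc", 1:4), paste0("f_slope_loc", 1:4),
         paste0("tau_loc", 1:4), "demarcation_cm", "watershed_cm", names(hemo))]
  })
}
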