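---
title: "Quantifying ICG fluorescence perfusion: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ICG fluorescence perfusion: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icgquant)
```

## The measurement problem

After esophagectomy, the gastric conduit is perfused almost entirely through
the right gastroepiploic artery; its tip (the fundus) is the watershed-distal,
worst-perfused region and the site of the anastomosis. An intravenous bolus
of indocyanine green imaged with a near-infrared camera shows dye arrival as
a rising fluorescence signal, but "how bright, how fast, how late" is not
quantified by eye. `icgquant` reduces a recording to per-location
time–intensity curves and three parameters per location: the influx
timepoint $\tau$, the mean post-influx slope $F_{slope}$, and the maximal
post-influx intensity $F_{max}$. All three are expected to deteriorate from
conduit base to fundus, and a near-zero fundus slope or a long non-perfused
tip segment marks a high-risk anastomosis.

## The per-trace algorithm

Given a raw ROI trace $F_i(t)$ sampled uniformly at the frame rate:

1. **Robust local-linear smoothing.** Every sample is replaced by the value
   at its own position of a weighted least-squares line over a centered
   window of `smoothing_span = 21` samples (the window slides one-sidedly
   into the trace at the ends so it always contains the 21 nearest samples;
   degree-1 local regression reproduces affine signals exactly, so a linear
   bolus rise is not biased). Weights are tricube in distance, multiplied by
   robust weights refined over 5 passes: residuals beyond
   `robust_cutoff = 6` times the robust residual scale get zero weight,
   residuals inside get bisquare weights. The scale is the median absolute
   residual by default ("sd" is available by configuration); a scale robust
   to the very outliers being rejected is the only self-consistent choice.
2. **Point-wise derivative.** Central differences (exact for quadratics) at
   interior samples, one-sided at the two ends, in intensity/s.
3. **Noise reference.** Mean $\mu_{noise,i}$ and standard deviation
   $\sigma_{noise,i}$ (n−1 denominator) of the derivative over the first
   `noise_window = 10` s, which the bolus must not yet have reached.
4. **Influx detection.** $\tau_i$ is the first sample, at or after the end
   of the noise window, whose derivative exceeds
   $\mu_{noise,i} + k\,\max(\sigma_{noise,i}, \sigma_{floor})$ with
   `influx_k = 5.5`, and that starts a run of `sustain_samples = 3`
   consecutive supra-threshold samples. The search never enters the noise
   window: the criterion is undefined on the data that defined it.
5. **Parameters.** $F_{slope}$ is the mean derivative over the half-open
   window $[\tau, \tau + 10\,\mathrm{s})$; $F_{max}$ the maximum of the
   smoothed trace over the closed window $[\tau, \tau + 50\,\mathrm{s}]$,
   truncated (and flagged `window_truncated`) when the recording ends
   earlier — intra-operative recordings are capped at 2–3 minutes and
   poorly perfused locations often do not peak in time.

### Numerical choices

* **Sustained crossing.** The literal criterion needs only one
  supra-threshold sample; requiring 3 consecutive samples guards against
  single-sample noise spikes and can be set to 1 to reproduce the literal
  rule. On smooth influx curves the two are practically identical.
* **Detection floor.** $\sigma_{floor}$ is `sigma_floor_frac = 1e-6` of the
  trace's intensity range. A genuinely flat noiseless baseline has
  $\sigma_{noise} = 0$; without the floor, any numerical ripple would fire
  the detector.
* **Robust-scale floor.** The smoother's residual scale is floored at
  $10^{-4}$ of the signal range. On noiseless smooth curves the median
  absolute residual collapses to the tiny fit bias, and a 6× cutoff on that
  scale would zero-weight entire curved regions; the floor sits far below
  any genuine outlier and far above numerical fit bias, so it only
  deactivates robust rejection where there is nothing to reject. In
  addition, each window's fitted value is clamped to that window's data
  range: a near-degenerate weight pattern (most of a window rejected) can
  otherwise extrapolate, and a local fit never needs to leave its data.
* **Window semantics.** Timestamps are compared with a `1e-9` s tolerance;
  the slope window is half-open in time, the max window closed. At 25 Hz
  and $\tau = 20$ s the slope window covers exactly samples 500–749.
* **Smoothing smear.** Detection operates on the smoothed derivative, so
  $\tau$ can lead or lag the analytic threshold crossing by up to half a
  span (0.42 s at 25 Hz). On realistic noisy traces the threshold is set by
  real noise and the measured onset error stays well inside ±0.5 s; the
  half-span bound is the worst case for noiseless slow rises.
* **$F_{max}$ series.** The maximum is taken on the smoothed trace by
  default (the raw maximum of a noisy trace is biased upward by the noise
  envelope); `fmax_series = "raw"` is available for noiseless analyses.
* **Equivariances.** Scaling a trace by $c>0$ scales $F_{max}$ and
  $F_{slope}$ by $c$ and leaves $\tau$ unchanged; adding a constant shifts
  $F_{max}$ only; delaying the bolus shifts $\tau$ only. These hold because
  the tricube weights, the robust cutoff (scale-relative) and the
  $\sigma$-threshold (scale-covariant) are all invariant under these
  transformations, and the test suite asserts them to `1e-6`.

## Preprocessing

**Flat-field correction.** Ring-light illumination falls off towards the
image corners, mimicking reduced perfusion there. The gain map is the
temporal mean of a uniform-target recording, optionally Gaussian-blurred
(`smoothing_sigma = 5` px, suppressing target texture without flattening
the vignette) and normalized to unit spatial mean; recordings are divided
by it pixel-wise.

**Gain-step normalization.** When camera settings are adjusted mid-recording
the signal jumps multiplicatively (gain/exposure scale the signal; they do
not offset it). Given a user-annotated change time, the post-change segment
is rescaled by the ratio of mean intensities over a reference span
immediately before versus after the change. The change time is annotated,
not auto-detected: automatic step detection on a rising bolus signal is
error-prone. The mean-ratio estimator is exact for locally constant signal
and has a bias proportional to the local slope across the reference span —
acceptable for the annotated, near-plateau cases it is meant for.

**Calibration.** Two annotated points on a metric ruler give
`pixels_per_cm`. The camera views the scene perpendicularly from a fixed
height, so a single isotropic scale is used; lens distortion and
perspective are out of scope.

## Geometry

Distances are **arc lengths along the annotated conduit centerline**, not
chords: the conduit is curved in the field of view and a chord would
systematically underestimate anatomical distance. The demarcation is
localized on the late-phase image (mean of the final 10 s, after flat-field
correction): by the end of the recording ICG has accumulated in all
perfused tissue, so perfused and non-perfused conduit separate cleanly. The
reference level is the median intensity (5 px disc means) along the
proximal third of the centerline, and the demarcation is the most distal
vertex whose local intensity still reaches `threshold_fraction = 0.25` of
that reference. There is no canonical operational definition of the visible
demarcation line, so the threshold is deliberately prominent, configurable
and logged; lowering it moves the demarcation distally or not at all (a
tested monotonicity). The watershed annotation is projected onto the
nearest centerline vertex (within 20 px) and its arc distance to the tip
reported.

## The synthetic generators

The generators define the study conditions under which the package is
validated; they are first-class, tested code.

**Kinetics.** Each location follows
$f(t) = B + A\,(1 - e^{-(t-t_0)/r})\,e^{-k(t-t_0)}$ for $t \ge t_0$, $B$
before. This is the simplest form producing both observed regimes: arterial
locations rise fast and wash out ($k > 0$), while the fundus rises late and
weakly and keeps accumulating because venous ligation suppresses clearance
($k = 0$). Defaults: base $t_0 = 12$ s, $A = 120$; fundus $t_0 = 20$ s,
$A = 45$, $k = 0$; rise constants 1.5–2 s; additive Gaussian sensor noise
$\sigma = 2$ on an 8-bit scale. The base onset sits 2 s after the 10 s
noise window deliberately: an onset at the window edge would leak
early-rise signal into the statistics that define the detection threshold.
No per-patient clinical traces exist to calibrate the noise level against;
$\sigma = 2$ is a plausible sensor-dominated choice.

**Phantom scenes.** A curved centerline crosses a 140×225 px frame at
16 px/cm (≈12.3 cm of conduit); conduit pixels take kinetics interpolated
by arc position between the four location anchors, with a 0.7 cm plateau
around each anchor — wider than the 300 px ROI radius (0.61 cm), so each
ROI samples exactly its location's kinetics while the tissue between
locations still transitions smoothly. Pixels within `demarcation_cm = 2` of
the tip keep baseline-only kinetics; the default fundus ROI sits at 3.0 cm
from the tip, proximal of the demarcated segment, as in recordings where a
demarcation is visible distal to the measurement site. Frames are
multiplied by a radial vignette (30% corner falloff), perturbed with
Gaussian noise and quantized to 8-bit integers — so written stacks
round-trip bit-exactly — and the generator emits the scene annotations, a
uniform-target recording for flat-field fitting, and bookkeeping ground
truth (per-ROI per-frame means of the rendered frames, analytic onsets,
window slopes and maxima, true demarcation and watershed arc distances).

**Cohorts.** Per-patient parameters are drawn from normals with the
observed group means/SDs ($F_{max}$ 129/129/123/51, SD 49/56/64/39) and
within-patient equicorrelation $\rho = 0.5$, left-clipped at zero. Clipping
(censoring at the sensor floor) is used rather than rejection truncation:
it keeps the group means at their configured values, whereas rejecting
negative draws from the fundus distribution (51 ± 39) would inflate its
mean by ≈7. Leakage patients (default 15%, 3 of 20) draw their fundus slope
uniformly from (0.02, 0.18) and demarcation distances around 4.5 cm;
non-leakage fundus slopes are bounded below at 0.25. The bounds make the
risk rule's recovery a construction guarantee at any noise level — a
deliberate property for testing the rule's wiring, not a claim about
clinical separability.

**What the generators do not emulate.** Recirculation peaks,
cardiac-output-dependent arrival dispersion, tissue scattering, motion, and
specular artifacts (e.g. measuring on a stapler line) are absent. Passing
recovery tests therefore demonstrates algorithmic correctness under the
stated model, not robustness to every clinical artifact; recordings with
camera motion must still be excluded upstream.

## The statistics layer

* **Normality:** D'Agostino–Pearson omnibus $K^2$ (skewness z after
  D'Agostino, kurtosis z after Anscombe–Glynn, $\chi^2_2$ reference),
  implemented from the published formulas and verified against an
  independent reference implementation.
* **Location effects:** one-way within-subject ANOVA from the explicit
  sums-of-squares decomposition, with sphericity-assuming and
  Greenhouse–Geisser corrected p-values; rows missing location 1 (conduit
  base intra-thoracic) are dropped complete-case and counted. Pairwise
  location contrasts are uncorrected paired t-tests, reported alongside the
  omnibus test; a Bonferroni factor can be applied by the caller.
* **Group comparisons:** pooled-variance unpaired t (Welch by option).
* **Hemodynamic association:** the stated procedure — a signed-rank test on
  standardized pairs — is a paired-difference test, not a correlation, and
  is reported with that caveat; Spearman's $\rho$ is computed alongside as
  the conventional alternative.
* **Power:** exact two-sided noncentral-t power for the paired design
  (n = 20, d = 0.66, $\alpha$ = 0.05 gives 79.9%, i.e. 80%); enrollment
  inflation is $\lceil n(1+a)\rceil$, reproducing 20 → 22 at 10% attrition
  (dividing by $1-a$ would give 23 and does not match the study
  arithmetic).
* **Risk rule:** strict `f_slope < 0.2` at the fundus, or no influx
  detected there, or (when a threshold is configured — none is published)
  `demarcation_cm` above it. The rule is monotone by construction.

## Problem sizes used in validation

The test suite validates onset/slope recovery on 200 seeded traces of 80 s
at 25 Hz (SNR 30–75), the phantom pipeline on a 1500-frame 140×225 px
scene, the Monte-Carlo power check on 200 000 simulated paired samples, and
the exhaustive oracles (ROI distance-sort, signed-rank sign enumeration,
ANOVA sums of squares) at the small sizes where exhaustion is exact. These
sizes give stable pass/fail behavior at desk scale; the measured onset
errors on the trace population are −0.29 to +0.09 s against the ±0.5 s
contract.

## Known limitations

* $\tau$ is referenced to the first recorded frame, not to injection time;
  the injection-to-recording offset is stored (`t0_offset`) but never added,
  so runs are reproducible from the recording alone.
* The 5.5σ criterion cannot detect rises whose peak derivative stays below
  the threshold — slow, weak influx at very low SNR is reported as
  "undetected" rather than guessed.
* The demarcation threshold (0.25 of the proximal reference) has no
  published counterpart; distances depend on it, which is why it is logged
  with every run.
* Cohort generation reproduces group-level moments, not joint physiology;
  hemodynamic columns are independent draws and carry no built-in
  association with the perfusion parameters.
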