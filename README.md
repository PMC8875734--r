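# icgquant

Quantitative analysis of indocyanine green (ICG) fluorescence angiography
for tissue perfusion assessment.

During esophagectomy with gastric tube reconstruction, most of the stomach's
arterial supply is ligated and the conduit's tip (the fundus, where the
anastomosis is made) depends on collateral flow from the right gastroepiploic
artery. Poor fundus perfusion is the major driver of anastomotic leakage.
Near-infrared imaging of an intravenous ICG bolus shows perfusion directly in
the operating room, but the raw video is interpreted subjectively. `icgquant`
turns such recordings into quantitative, per-location perfusion parameters
and the cohort-level statistics needed to relate them to outcomes.

## The algorithm

From a recording `F(x, y, t)` and four circular regions of interest (ROIs) of
300 pixels placed from the conduit base to the fundus, the package computes
per-location time–intensity curves `F_i(t)` (mean ROI intensity per frame,
after flat-field illumination correction) and derives, per location *i*:

1. **Smoothing** — robust local linear regression (span 21 samples, tricube
   weights, iterative zero-weighting of residuals beyond 6× the robust
   residual scale).
2. **Point-wise derivative** — central differences of the smoothed trace.
3. **Noise reference** — mean `μ_noise,i` and standard deviation `σ_noise,i`
   of the derivative over the first 10 s (pre-influx baseline).
4. **Influx timepoint `τ_i`** — the first time (after the baseline window) at
   which the derivative exceeds `μ_noise,i + 5.5 σ_noise,i` sustainedly.
5. **`F_slope,i`** — mean derivative over the 10 s following `τ_i`
   (intensity/s).
6. **`F_max,i`** — maximum smoothed intensity over `[τ_i, τ_i + 50 s]`
   (truncated, and flagged, when the recording ends earlier).

A geometry module measures, along a user-annotated conduit centerline
calibrated against a metric ruler in the field of view, the arc distance
from the late-phase fluorescence demarcation to the fundus tip and from the
surgeon-marked watershed to the tip (cm). A statistics module reproduces the
study-level layer: D'Agostino–Pearson normality, repeated-measures ANOVA
across locations with paired contrasts, unpaired t comparisons between
leakage groups, signed-rank association checks, noncentral-*t* power
analysis, patient-flow accounting, and a leakage-risk rule (`F_slope < 0.2`
at the fundus, undetected influx, or a long demarcation distance).

Because no clinical recordings ship with the package, a synthetic module
generates traces, full phantom videos and cohorts with stored ground truth;
every stage of the pipeline is tested against those generators.

## Worked example

```r
library(icgquant)

spec   <- kinetic_spec()                      # 4-location defaults, 25 Hz, 80 s
traces <- lapply(1:4, generate_trace, spec = spec)
params <- lapply(traces, quantify_trace)
for (p in params) print(p)
#> <perfusion_params> loc 1: tau = 11.8 s, F_max = 121.6, F_slope = 10.73/s
#> <perfusion_params> loc 2: tau = 12.8 s, F_max = 116.9, F_slope = 10.36/s
#> <perfusion_params> loc 3: tau = 14.8 s, F_max = 102.4, F_slope = 9.08/s
#> <perfusion_params> loc 4: tau = 20 s, F_max = 56.61, F_slope = 4.331/s
```

The fundus (location 4) fills ~8 s later, less than half as brightly and at
less than half the slope of the conduit base (location 1) — the ischemia
gradient the parameters are designed to expose. The cohort layer on a
20-patient synthetic cohort:

```r
cohort <- generate_cohort(n_patients = 20, seed = 1)
print(cohort_report(cohort))
#> <cohort_report> n = 20 patients
#>   f_max    RM-ANOVA F(3,57) = 28.932, p = 1.69e-11 (GG p = 1.39e-09)
#>   f_slope  RM-ANOVA F(3,57) = 22.544, p = 9.46e-10 (GG p = 1.21e-08)
#>   tau      RM-ANOVA F(3,57) = 47.906, p = 1.36e-15 (GG p = 9.28e-10)
#>   f_slope_loc4   leakage vs non-leakage: t = -3.262, p = 0.00433
#>   demarcation_cm leakage vs non-leakage: t = 11.921, p = 5.61e-10
#>   watershed_cm   leakage vs non-leakage: t = 1.222, p = 0.238
#>   high-risk flags: 3 of 20 patients
```

A full phantom video pipeline (render → flat-field → extract → quantify →
geometry) is wired behind `run_simulate()` / `run_quantify()` /
`run_stats()`, also exposed as a command line tool:

```sh
Rscript inst/cli/icgquant.R simulate --seed 1 --out phantom/
Rscript inst/cli/icgquant.R quantify --input phantom/stack.tif \
    --rois phantom/annotations.json --profile phantom/profile.tif \
    --frame-rate 25 --out results/
```

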