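Package: icgquant
Title: Quantitative Indocyanine Green Fluorescence Perfusion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies tissue perfusion from near-infrared indocyanine green
    (ICG) fluorescence video recordings, as used for intra-operative
    assessment of gastric conduit perfusion during esophagectomy. Extracts
    region-of-interest time-intensity traces from multi-frame recordings,
    applies robust local-regression smoothing and point-wise differentiation,
    detects the bolus influx timepoint by a derivative noise-threshold
    criterion, and derives the perfusion parameters F_max, F_slope and tau
    per location. Includes flat-field illumination correction, pixel-to-cm
    calibration, arc-length measurement of the perfusion demarcation and
    watershed distances along the conduit centerline, a cohort statistics
    layer (normality testing, repeated-measures ANOVA, paired and unpaired
    comparisons, signed-rank tests, noncentral-t power analysis, and a
    leakage-risk rule), and seeded synthetic generators for traces, phantom
    videos and cohorts that make every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
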