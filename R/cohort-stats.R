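#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the z-transformed sample skewness (D'Agostino) and kurtosis
#' (Anscombe-Glynn) into the omnibus statistic K2 = z1^2 + z2^2, referred to
#' a chi-squared distribution with 2 degrees of freedom.
#'
#' @param values Numeric sample, n >= 8.
#' @return List with `k2`, `p_value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(values) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 8L) abort_input("D'Agostino-Pearson needs at least 8 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) abort_compute("zero variance sample")
  b1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2

  # skewness z (D'Agostino 1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis z (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) / sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(k2 = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' One-way repeated-measures ANOVA across locations
#'
#' Within-subject one-way ANOVA on a patients x locations matrix:
#' `F = MS_condition / MS_error` with df `(k-1)` and `(n-1)(k-1)` under
#' sphericity; a Greenhouse-Geisser corrected p-value is reported alongside.
#' Rows with any missing value (e.g. patients whose Location 1 lay
#' intra-thoracically) are dropped and counted.
#'
#' @param matrix Numeric matrix, one row per patient, one column per
#'   location; `NA`s trigger complete-case deletion.
#' @return List with `f`, `p_value`, `df`, `p_gg`, `gg_epsilon`,
#'   `n_complete`, `n_dropped`.
#' @export
repeated_measures_anova <- function(matrix) {
  y <- as.matrix(matrix)
  complete <- stats::complete.cases(y)
  n_dropped <- sum(!complete)
  y <- y[complete, , drop = FALSE]
  n <- nrow(y); k <- ncol(y)
  if (n < 3L) abort_input("repeated-measures ANOVA needs >= 3 complete patients")
  grand <- mean(y)
  ss_cond <- n * sum((colMeans(y) - grand)^2)
  ss_subj <- k * sum((rowMeans(y) - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  f <- if (ms_err > 0) ms_cond / ms_err else if (ms_cond == 0) 0 else Inf
  p <- if (ms_err > 0) pf(f, df1, df2, lower.tail = FALSE) else if (ms_cond == 0) 1 else 0
  if (ss_cond == 0) { f <- 0; p <- 1 }
  # Greenhouse-Geisser epsilon from the double-centered covariance matrix
  s <- cov(y)
  sc <- s - outer(rowMeans(s), rep(1, k)) - outer(rep(1, k), colMeans(s)) + mean(s)
  eps <- sum(diag(sc))^2 / ((k - 1) * sum(sc^2))
  eps <- min(max(eps, 1 / (k - 1)), 1)
  p_gg <- if (ms_err > 0) pf(f, eps * df1, eps * df2, lower.tail = FALSE) else p
  if (ss_cond == 0) p_gg <- 1
  list(f = f, p_value = p, df = c(df1, df2), p_gg = p_gg, gg_epsilon = eps,
       n_complete = n, n_dropped = n_dropped)
}

#' Paired contrast between two locations
#'
#' Two-sided paired t-test on the within-patient differences between two
#' columns of the patients x locations matrix (pairwise p-values are
#' reported uncorrected, alongside the omnibus ANOVA; a Bonferroni factor
#' can be applied by the caller).
#'
#' @param matrix Patients x locations matrix.
#' @param loc_a,loc_b Column indices to contrast.
#' @return List with `t`, `p_value`, `df`, `mean_diff`, `n`.
#' @export
paired_location_contrast <- function(matrix, loc_a, loc_b) {
  y <- as.matrix(matrix)
  d <- y[, loc_a] - y[, loc_b]
  d <- d[is.finite(d)]
  if (length(d) < 3L) abort_input("paired contrast needs >= 3 paired observations")
  if (sd(d) == 0) abort_compute("zero-variance paired differences")
  ht <- t.test(d)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), mean_diff = mean(d), n = length(d))
}

#' Unpaired two-sample t-test (leakage vs non-leakage groups)
#'
#' @param group_a,group_b Numeric samples, each n >= 2.
#' @param welch Use the Welch unequal-variance form instead of the
#'   pooled-variance default.
#' @return List with `t`, `p_value`, `df`, `mean_a`, `mean_b`.
#' @export
unpaired_ttest <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    abort_input("both groups need at least 2 observations")
  if (sd(group_a) == 0 && sd(group_b) == 0)
    abort_compute("zero pooled variance")
  ht <- t.test(group_a, group_b, var.equal = !welch)
  list(t = unname(ht$statistic), p_value = ht$p.value, df = unname(ht$parameter),
       mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Wilcoxon signed-rank test on paired values
#'
#' Zero differences are discarded; `W` is the sum of the ranks of the
#' positive differences. The p-value is exact (signed-rank distribution)
#' for up to 25 non-zero differences without ties, and a normal
#' approximation with continuity and tie correction otherwise.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `w`, `p_value`, `n` (non-zero differences), `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) abort_input("x and y must be paired (equal length)")
  d <- x - y
  d <- d[is.finite(d)]
  nz <- d[d != 0]
  n <- length(nz)
  if (n < 6L) abort_input("needs at least 6 non-zero paired differences")
  r <- rank(abs(nz))
  w <- sum(r[nz > 0])
  has_ties <- anyDuplicated(abs(nz)) > 0
  if (n <= 25L && !has_ties) {
    p_le <- psignrank(w, n)
    p_ge <- psignrank(w - 1, n, lower.tail = FALSE)
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(w = w, p_value = p, n = n, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  list(w = w, p_value = min(1, 2 * pnorm(-abs(z))), n = n, exact = FALSE)
}

#' Power of a two-sided paired t-test
#'
#' Closed form via the noncentral t distribution:
#' `power = P(|T'| > t_crit)` with `T'` noncentral t with `n - 1` degrees of
#' freedom and noncentrality `d * sqrt(n)`.
#'
#' @param n Number of pairs (patients), >= 2.
#' @param effect_size Standardized effect size d >= 0.
#' @param alpha Two-sided significance level in (0, 1), default 0.05.
#' @return Power in \[0, 1\].
#' @export
power_paired_t <- function(n, effect_size, alpha = 0.05) {
  if (n < 2L) abort_input("n must be >= 2")
  if (alpha <= 0 || alpha >= 1) abort_input("alpha must be in (0, 1)")
  if (effect_size < 0) abort_input("effect_size must be >= 0")
  df <- n - 1
  ncp <- effect_size * sqrt(n)
  tcrit <- qt(1 - alpha / 2, df)
  pt(tcrit, df, ncp = ncp, lower.tail = FALSE) + pt(-tcrit, df, ncp = ncp)
}

#' Inflate a sample size for expected attrition
#'
#' `ceiling(n * (1 + attrition_fraction))`: with the study's 10% allowance,
#' 20 analyzable patients require 22 enrolled.
#'
#' @param n Required analyzable patients, >= 1.
#' @param attrition_fraction Expected missing/unevaluable fraction in \[0, 1).
#' @return Enrollment count (integer).
#' @export
inflate_sample <- function(n, attrition_fraction) {
  if (n < 1L) abort_input("n must be >= 1")
  if (attrition_fraction < 0 || attrition_fraction >= 1)
    abort_input("attrition_fraction must be in [0, 1)")
  # round first: 100 * 1.1 is 110.0000...01 in floating point
  as.integer(ceiling(round(n * (1 + attrition_fraction), 9)))
}

#' Patient-flow accounting
#'
#' Counts enrollment and the two exclusion categories (no imaging
#' performed; images unevaluable) and derives the evaluable count.
#'
#' @param roster Data frame with columns `patient_id`,
#'   `excluded_no_imaging`, `excluded_unevaluable` (logical; mutually
#'   exclusive per patient).
#' @return List with `enrolled`, `excluded_no_imaging`,
#'   `excluded_unevaluable`, `evaluable`.
#' @export
apply_patient_flow <- function(roster) {
  if (nrow(roster) == 0L) abort_input("empty roster")
  a <- as.logical(roster$excluded_no_imaging)
  b <- as.logical(roster$excluded_unevaluable)
  if (any(a & b)) abort_input("conflicting exclusion flags in roster")
  list(enrolled = nrow(roster),
       excluded_no_imaging = sum(a),
       excluded_unevaluable = sum(b),
       evaluable = nrow(roster) - sum(a) - sum(b))
}

#' Leakage-risk rule from fundus kinetics and demarcation distance
#'
#' A patient is flagged high-risk when the fundus (location 4) mean slope
#' falls strictly below `slope_threshold` (default 0.2 intensity/s, the
#' value below which all leakage cases fell), when no influx was detected
#' at the fundus at all, or - if a distance threshold is configured - when
#' the demarcation-to-fundus distance exceeds it. No published cut-off
#' exists for the distance, so that rule is disabled by default.
#'
#' @param params_loc4 [perfusion_params()] of location 4.
#' @param geometry A [geometry_measures()] or `NULL`.
#' @param slope_threshold Strict lower slope bound (intensity/s).
#' @param distance_threshold Demarcation distance bound in cm, or `NULL`
#'   (disabled).
#' @return List with `high_risk` (logical) and `reasons` (character vector
#'   naming every triggered rule).
#' @export
classify_risk <- function(params_loc4, geometry = NULL, slope_threshold = 0.2,
                          distance_threshold = NULL) {
  if (is.null(params_loc4)) abort_input("location 4 parameters are required")
  reasons <- character(0)
  if (!params_loc4$influx_detected) {
    reasons <- c(reasons, "no_influx")
  } else if (params_loc4$f_slope < slope_threshold) {
    reasons <- c(reasons, "slope")
  }
  if (!is.null(distance_threshold) && !is.null(geometry) &&
      isTRUE(geometry$demarcation_to_fundus_cm > distance_threshold)) {
    reasons <- c(reasons, "demarcation_distance")
  }
  list(high_risk = length(reasons) > 0, reasons = reasons)
}

#' Read a cohort table from CSV
#'
#' Expected columns: `patient_id`, `leakage`, `f_max_loc1..4`,
#' `f_slope_loc1..4`, `tau_loc1..4`, `demarcation_cm`, `watershed_cm` and
#' optional hemodynamics (`MAP`, `HR`, `SBP`, `DBP`, `CO`, `SV`, `SVV`,
#' `CI`).
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) abort_input("no such file: ", path)
  df <- read.csv(path)
  required <- c("patient_id", "leakage",
                paste0("f_max_loc", 1:4), paste0("f_slope_loc", 1:4),
                paste0("tau_loc", 1:4), "demarcation_cm", "watershed_cm")
  missing <- setdiff(required, names(df))
  if (length(missing))
    abort_input("cohort CSV lacks required columns: ", paste(missing, collapse = ", "))
  df
}

HEMO_COLS <- c("MAP", "HR", "SBP", "DBP", "CO", "SV", "SVV", "CI")

#' Full cohort statistics report
#'
#' Reproduces the study's statistical layer on a cohort table: normality
#' per parameter, repeated-measures ANOVA with pairwise location contrasts
#' for F_max, F_slope and tau, leakage-group comparisons (unpaired t) of
#' the fundus slope and both distances, hemodynamic association checks
#' (signed-rank on standardized pairs, plus Spearman correlations as the
#' conventional alternative) and the per-patient risk flags.
#'
#' @param cohort Data frame in the [read_cohort_csv()] schema.
#' @param slope_threshold Risk-rule slope threshold (default 0.2).
#' @param distance_threshold Optional risk-rule distance threshold (cm).
#' @return List of class `cohort_report`.
#' @export
cohort_report <- function(cohort, slope_threshold = 0.2, distance_threshold = NULL) {
  out <- list(n = nrow(cohort))
  params <- c(f_max = "f_max_loc", f_slope = "f_slope_loc", tau = "tau_loc")
  out$anova <- lapply(params, function(prefix) {
    m <- as.matrix(cohort[paste0(prefix, 1:4)])
    res <- repeated_measures_anova(m)
    res$contrasts_vs_loc4 <- lapply(1:3, function(l) paired_location_contrast(m, l, 4))
    res
  })
  out$normality <- lapply(params, function(prefix) {
    vals <- as.matrix(cohort[paste0(prefix, 1:4)])
    tryCatch(dagostino_pearson(as.vector(vals)), icgquant_error = function(e) NULL)
  })
  leak <- as.logical(cohort$leakage)
  out$group_comparisons <- if (sum(leak) >= 2 && sum(!leak) >= 2) {
    list(
      f_slope_loc4 = unpaired_ttest(cohort$f_slope_loc4[leak], cohort$f_slope_loc4[!leak]),
      demarcation_cm = unpaired_ttest(cohort$demarcation_cm[leak], cohort$demarcation_cm[!leak]),
      watershed_cm = unpaired_ttest(cohort$watershed_cm[leak], cohort$watershed_cm[!leak])
    )
  } else "not computable: fewer than 2 patients in a group"
  hemo <- intersect(HEMO_COLS, names(cohort))
  if (length(hemo)) {
    zscore <- function(v) (v - mean(v)) / sd(v)
    out$hemodynamics <- lapply(stats::setNames(hemo, hemo), function(hc) {
      lapply(c(f_max = "f_max_loc4", f_slope = "f_slope_loc4", tau = "tau_loc4"),
             function(pc) {
               x <- zscore(cohort[[hc]]); y <- zscore(cohort[[pc]])
               sr <- tryCatch(wilcoxon_signed_rank(x, y),
                              icgquant_error = function(e) NULL)
               list(signed_rank = sr,
                    spearman_rho = stats::cor(cohort[[hc]], cohort[[pc]],
                                              method = "spearman"))
             })
    })
  }
  out$risk <- lapply(seq_len(nrow(cohort)), function(i) {
    p4 <- perfusion_params(4L, tau = cohort$tau_loc4[i], f_max = cohort$f_max_loc4[i],
                           f_slope = cohort$f_slope_loc4[i],
                           influx_detected = !is.na(cohort$tau_loc4[i]))
    g <- geometry_measures(cohort$demarcation_cm[i] > 0, cohort$demarcation_cm[i],
                           cohort$watershed_cm[i])
    c(list(patient_id = cohort$patient_id[i], leakage = leak[i]),
      classify_risk(p4, g, slope_threshold, distance_threshold))
  })
  class(out) <- "cohort_report"
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> n = %d patients\n", x$n))
  for (nm in names(x$anova)) {
    a <- x$anova[[nm]]
    cat(sprintf("  %-8s RM-ANOVA F(%d,%d) = %.3f, p = %.3g (GG p = %.3g)\n",
                nm, a$df[1], a$df[2], a$f, a$p_value, a$p_gg))
  }
  if (is.character(x$group_comparisons)) {
    cat("  leakage-group comparisons:", x$group_comparisons, "\n")
  } else {
    for (nm in names(x$group_comparisons)) {
      g <- x$group_comparisons[[nm]]
      cat(sprintf("  %-14s leakage vs non-leakage: t = %.3f, p = %.3g\n",
                  nm, g$t, g$p_value))
    }
  }
  flagged <- sum(vapply(x$risk, function(r) r$high_risk, logical(1)))
  cat(sprintf("  high-risk flags: %d of %d patients\n", flagged, x$n))
  invisible(x)
}
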