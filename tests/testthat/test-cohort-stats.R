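test_that("D'Agostino-Pearson matches an independent reference implementation", {
  # fixed normal-ish sample; reference K2/p computed independently with the
  # same published omnibus formulas
  x <- c(53.047171, 39.600159, 57.504512, 59.405647, 30.489648, 36.978205,
         51.278404, 46.837574, 49.831988, 41.469561, 58.79398, 57.777919,
         50.660307, 61.272412, 54.675093, 41.407075, 53.687508, 40.411174,
         58.784503, 49.500741, 48.151376, 43.190705, 62.225413, 48.454705,
         45.716722, 46.478664, 55.323092, 53.654441, 54.127326, 54.30821,
         71.416476, 45.93585, 44.877573, 41.862273, 56.159794, 61.289723,
         48.860525, 41.598435, 41.755188, 56.505928)
  res <- dagostino_pearson(x)
  expect_equal(res$k2, 0.11548184829749972, tolerance = 1e-9)
  expect_equal(res$p_value, 0.9438944560219802, tolerance = 1e-9)

  y <- c(2.667405, 2.781728, 2.168166, 0.146057, 2.268135, 2.708676, 2.244079,
         0.560098, 0.641872, 0.331472, 0.708727, 0.04228, 0.334713, 2.630114,
         7.991513, 1.127076, 0.568079, 0.795513, 0.722684, 0.259267, 2.16665,
         2.751698, 3.015618, 10.619766, 4.21332, 3.289732, 2.086983, 1.185048,
         0.088907, 1.913206)
  res_y <- dagostino_pearson(y)
  expect_equal(res_y$k2, 30.48707179477944, tolerance = 1e-9)
  expect_equal(res_y$p_value, 2.397819430116754e-07, tolerance = 1e-6)

  expect_error(dagostino_pearson(rnorm(5)), class = "icgquant_input_error")
  expect_error(dagostino_pearson(rep(1, 20)), class = "icgquant_compute_error")
})

test_that("D'Agostino-Pearson is calibrated under the null and powered against skew", {
  set.seed(101)
  p_norm <- replicate(100, dagostino_pearson(rnorm(500))$p_value)
  expect_gte(mean(p_norm > 0.05), 0.90)
  p_exp <- replicate(100, dagostino_pearson(rexp(500))$p_value)
  expect_gte(mean(p_exp < 0.01), 0.95)
})

test_that("repeated-measures ANOVA matches hand and aov computations", {
  # identical columns: no condition effect
  y <- matrix(rep(c(1, 3, 5, 9), 3), ncol = 3)
  res <- repeated_measures_anova(y)
  expect_equal(res$f, 0)
  expect_equal(res$p_value, 1)

  # 4 x 3 toy matrix against the definitional sums of squares
  y <- matrix(c(5, 6, 7, 8,
                7, 9, 10, 12,
                6, 7, 10, 9), ncol = 3)
  res <- repeated_measures_anova(y)
  expect_equal(res$f, brute_force_rm_anova_f(y), tolerance = 1e-9)
  expect_identical(res$df, c(2, 6))

  # random matrices against stats::aov with a subject error stratum
  set.seed(33)
  for (i in 1:5) {
    n <- sample(4:8, 1); k <- sample(3:4, 1)
    y <- matrix(rnorm(n * k, 10, 3), n, k)
    long <- data.frame(v = as.vector(y),
                       subj = factor(rep(seq_len(n), k)),
                       cond = factor(rep(seq_len(k), each = n)))
    fit <- summary(stats::aov(v ~ cond + Error(subj), data = long))
    f_aov <- fit[["Error: Within"]][[1]]["cond", "F value"]
    expect_equal(repeated_measures_anova(y)$f, f_aov, tolerance = 1e-9)
  }

  # complete-case handling of a missing location 1
  y_na <- matrix(rnorm(24), 6, 4)
  y_na[2, 1] <- NA
  res <- repeated_measures_anova(y_na)
  expect_identical(res$n_complete, 5L)
  expect_identical(res$n_dropped, 1L)
  expect_error(repeated_measures_anova(y_na[1:3, ]), class = "icgquant_input_error")
})

test_that("paired contrasts reduce to the closed-form t on differences", {
  a <- c(12.1, 14.3, 11.8, 15.2, 13.9)
  b <- c(10.4, 13.1, 12.0, 13.8, 12.2)
  m <- cbind(a, b)
  res <- paired_location_contrast(m, 1, 2)
  d <- a - b
  t_closed <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$t, t_closed, tolerance = 1e-12)
  swapped <- paired_location_contrast(m, 2, 1)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p_value, res$p_value)
  expect_error(paired_location_contrast(cbind(a, a), 1, 2),
               class = "icgquant_compute_error")
})

test_that("unpaired t-test gives the pooled-variance textbook value", {
  res <- unpaired_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.674235, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 0.02131164, tolerance = 1e-6)
  expect_equal(unpaired_ttest(c(4, 5, 6), c(1, 2, 3))$t, -res$t)
  same <- unpaired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(unpaired_ttest(c(2, 2), c(2, 2)), class = "icgquant_compute_error")
})

test_that("signed-rank exact p matches full sign enumeration", {
  x <- c(125, 115, 130, 140, 140, 115, 140, 125)
  y <- c(110, 122, 125, 120, 140, 124, 123, 137)
  res <- wilcoxon_signed_rank(x, y)
  expect_true(res$exact)
  expect_equal(res$p_value, enum_wilcoxon_p((x - y)[(x - y) != 0]), tolerance = 1e-12)

  # property over random tie-free cases up to n = 12
  set.seed(55)
  for (i in 1:8) {
    n <- sample(6:12, 1)
    d <- round(rnorm(n, 0.4, 1), 6)
    res <- wilcoxon_signed_rank(d, rep(0, n))
    expect_equal(res$p_value, enum_wilcoxon_p(d), tolerance = 1e-12)
  }

  expect_equal(wilcoxon_signed_rank(x, y)$p_value, wilcoxon_signed_rank(y, x)$p_value)
  expect_error(wilcoxon_signed_rank(x, x), class = "icgquant_input_error")

  # above the exact limit the normal approximation takes over
  set.seed(56)
  big <- rnorm(30, 0.5)
  res_big <- wilcoxon_signed_rank(big, rep(0, 30))
  expect_false(res_big$exact)
  ref <- stats::wilcox.test(big, exact = FALSE, correct = TRUE)
  expect_equal(res_big$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("paired-test power follows the noncentral t and is monotone", {
  expect_equal(power_paired_t(20, 0), 0.05, tolerance = 1e-6)
  ref <- stats::power.t.test(n = 20, delta = 0.66, sd = 1, type = "paired")$power
  # power.t.test drops the negligible opposite-tail rejection mass
  expect_equal(power_paired_t(20, 0.66), ref, tolerance = 1e-5)
  p_n <- vapply(c(10, 15, 20, 30, 50), power_paired_t, numeric(1), effect_size = 0.5)
  expect_true(all(diff(p_n) > 0))
  p_d <- vapply(c(0.2, 0.4, 0.66, 1), function(d) power_paired_t(20, d), numeric(1))
  expect_true(all(diff(p_d) > 0))
  expect_error(power_paired_t(1, 0.5), class = "icgquant_input_error")
})

test_that("sample-size inflation and patient flow reproduce the enrollment arithmetic", {
  expect_identical(inflate_sample(20, 0.10), 22L)
  expect_identical(inflate_sample(20, 0), 20L)
  expect_identical(inflate_sample(100, 0.10), 110L)

  roster <- data.frame(patient_id = 1:26,
                       excluded_no_imaging = c(rep(TRUE, 4), rep(FALSE, 22)),
                       excluded_unevaluable = c(rep(FALSE, 24), TRUE, TRUE))
  flow <- apply_patient_flow(roster)
  expect_identical(flow$evaluable, 20L)
  expect_identical(flow$excluded_no_imaging, 4L)

  none <- data.frame(patient_id = 1:5, excluded_no_imaging = FALSE,
                     excluded_unevaluable = FALSE)
  expect_identical(apply_patient_flow(none)$evaluable, 5L)

  set.seed(77)
  r <- data.frame(patient_id = 1:40,
                  excluded_no_imaging = runif(40) < 0.2,
                  excluded_unevaluable = FALSE)
  r$excluded_unevaluable[!r$excluded_no_imaging] <- runif(sum(!r$excluded_no_imaging)) < 0.1
  flow <- apply_patient_flow(r)
  expect_identical(flow$evaluable,
                   sum(!r$excluded_no_imaging & !r$excluded_unevaluable))
  bad <- data.frame(patient_id = 1, excluded_no_imaging = TRUE,
                    excluded_unevaluable = TRUE)
  expect_error(apply_patient_flow(bad), class = "icgquant_input_error")
})

test_that("the risk rule is strict, covers undetected influx, and is monotone", {
  p <- function(fs) perfusion_params(4L, tau = 25, f_max = 50, f_slope = fs,
                                     influx_detected = TRUE)
  expect_true(classify_risk(p(0.15))$high_risk)
  expect_identical(classify_risk(p(0.15))$reasons, "slope")
  expect_false(classify_risk(p(0.2))$high_risk)    # boundary not flagged
  expect_true(classify_risk(perfusion_params(4L))$high_risk)
  expect_identical(classify_risk(perfusion_params(4L))$reasons, "no_influx")

  g <- geometry_measures(TRUE, 5, 7)
  both <- classify_risk(p(0.1), g, distance_threshold = 4)
  expect_setequal(both$reasons, c("slope", "demarcation_distance"))
  # monotone: decreasing slope / increasing distance never clears a flag
  fs_grid <- seq(0.3, 0.01, by = -0.01)
  flags <- vapply(fs_grid, function(f) classify_risk(p(f))$high_risk, logical(1))
  expect_true(all(diff(flags) >= 0))
})

test_that("cohort report runs the full layer on a generated cohort", {
  cohort <- generate_cohort(n_patients = 20, seed = 4L)
  rep <- cohort_report(cohort)
  expect_s3_class(rep, "cohort_report")
  expect_lt(rep$anova$f_max$p_value, 0.001)
  expect_lt(rep$anova$tau$p_value, 0.01)
  expect_false(is.character(rep$group_comparisons))
  expect_lt(rep$group_comparisons$demarcation_cm$p_value, 0.01)
  flagged <- vapply(rep$risk, function(r) r$high_risk, logical(1))
  expect_identical(flagged, cohort$leakage)

  no_leak <- generate_cohort(n_patients = 12, leakage_fraction = 0, seed = 5L)
  rep2 <- cohort_report(no_leak)
  expect_true(is.character(rep2$group_comparisons))
})
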