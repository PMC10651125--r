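test_that("peak intensity finds band maxima with the documented tie rule", {
  axis <- seq(2800, 3050, by = 1)
  sp <- raman_spectrum(axis, eval_bands(axis, list(band_spec(2930, 45, 3))))
  expect_equal(peak_intensity(sp, 2930), 3, tolerance = 0.01)
  flat <- raman_spectrum(axis, rep(0, length(axis)))
  expect_equal(peak_intensity(flat, 2930), 0)
  # two equal maxima in the window: value at the lower wavenumber is taken
  y <- rep(0, length(axis)); y[axis == 2925] <- 2; y[axis == 2935] <- 2
  expect_equal(peak_intensity(raman_spectrum(axis, y), 2930), 2)
  expect_error(peak_intensity(sp, 5000), "does not intersect")
  expect_gt(peak_intensity(sp, 2930, mode = "integral"), 0)
})

test_that("barcode extracts six peaks and a scale-invariant ratio", {
  cfg <- cohort_config(noise_sd = 0, cosmic_ray_rate = 0,
                       baseline_amplitude = 0, amp_jitter_sd = 0)
  sp <- simulate_spectrum(cfg, 2.34, seed = 2)
  bc <- barcode(sp)
  expect_named(bc$peaks, c("I1266", "I1452", "I1660", "I2850", "I2880",
                           "I2930"))
  expect_equal(bc$ratio, 2.34, tolerance = 0.05)
  scaled <- raman_spectrum(sp$wavenumber, 7 * sp$intensity)
  expect_equal(barcode(scaled)$ratio, bc$ratio, tolerance = 1e-12)
  # equal bands -> ratio 1
  sp1 <- simulate_spectrum(cfg, 1, seed = 2)
  expect_equal(barcode(sp1)$ratio, 1, tolerance = 0.05)
  # missing coverage and zero denominator are rejected
  short <- crop_region(sp, 2800, 3200)
  expect_error(barcode(short), "1266")
  axis <- seq(500, 3500, by = 2)
  zero2850 <- raman_spectrum(axis,
                             eval_bands(axis, list(band_spec(1266, 25, 1,
                                                             mix = 0))))
  expect_error(barcode(zero2850), "nonpositive")
})

test_that("boxplot summary follows the interpolated-quartile convention", {
  b <- boxplot_summary(1:8)
  expect_equal(b$median, 4.5)
  expect_equal(b$q1, 2.75)
  expect_equal(b$q3, 6.25)
  expect_equal(b$iqr, 3.5)
  expect_equal(b$whisker_lo, 1)  # clipped to the data extreme
  expect_equal(b$whisker_hi, 8)
  expect_length(b$outliers, 0)
  same <- boxplot_summary(rep(5, 6))
  expect_equal(same$iqr, 0)
  expect_length(same$outliers, 0)
  out <- boxplot_summary(c(1:10, 100))
  expect_equal(out$outliers, 100)
  expect_error(boxplot_summary(1:3), ">= 4")
})

test_that("calibrated generator draws reproduce the printed TBI median", {
  p <- lognormal_params(2.34, 0.63)
  draws <- ramanTBI:::with_seed(6, rlnorm(1e4, p$mu, p$sigma))
  expect_equal(unname(boxplot_summary(draws)$median), 2.34,
               tolerance = 0.02)
})

test_that("ROC AUC agrees with brute-force pair counting and sweeps", {
  r <- roc_auc(c(3, 2, 1, 2), c("p", "p", "n", "n"), positive = "p")
  expect_equal(r$auc, 0.875)
  expect_equal(r$auc, brute_force_auc(c(3, 2, 1, 2),
                                      c("p", "p", "n", "n"), "p"))
  expect_equal(r$auc, r$auc_trapezoid, tolerance = 1e-10)
  # perfect separation
  perf <- roc_auc(c(5, 6, 7, 1, 2), rep(c("p", "n"), c(3, 2)),
                  positive = "p")
  expect_equal(perf$auc, 1.0)
  # curve endpoints and monotonicity
  expect_equal(perf$curve$sensitivity[1], 0)
  expect_true(all(diff(perf$curve$sensitivity) >= 0))
  expect_true(all(diff(1 - perf$curve$specificity) >= 0))
  expect_error(roc_auc(1:3, c("p", "p", "p")), "positive and one negative")
})

test_that("AUC equivalence and monotone invariance hold on random inputs", {
  set.seed(33)
  for (i in 1:200) {
    n <- sample(6:40, 1)
    scores <- sample(round(rnorm(n), 1))  # ties likely
    labels <- sample(c("p", "n"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels, positive = "p")
    expect_equal(r$auc, r$auc_trapezoid, tolerance = 1e-10)
    expect_equal(r$auc, brute_force_auc(scores, labels, "p"))
    # strictly monotone transform leaves AUC unchanged
    r2 <- roc_auc(exp(scores), labels, positive = "p")
    expect_equal(r2$auc, r$auc, tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(55)
  scores <- rnorm(60) + rep(c(0, 1), each = 30)
  labels <- rep(c("n", "p"), each = 30)
  r <- roc_auc(scores, labels, positive = "p")
  ref <- pROC::auc(pROC::roc(labels, scores, levels = c("n", "p"),
                             direction = "<", quiet = TRUE))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("random scores give chance-level AUC", {
  set.seed(9)
  scores <- rnorm(400)
  labels <- rep(c("p", "n"), each = 200)
  r <- roc_auc(scores, labels, positive = "p")
  # sd of U-based AUC under the null ~ sqrt((n1+n2+1)/(12 n1 n2))
  null_sd <- sqrt((400 + 1) / (12 * 200 * 200))
  expect_lt(abs(r$auc - 0.5), 3 * null_sd)
})

test_that("confusion metrics follow the standard formulas with NA guards", {
  cm <- matrix(c(8, 1, 2, 9), 2, 2,
               dimnames = list(true = c("control", "TBI"),
                               predicted = c("control", "TBI")))
  # TP=9 FN=1 TN=8 FP=2
  met <- confusion_metrics(cm, positive = "TBI")
  expect_equal(met$sensitivity, 0.9)
  expect_equal(met$specificity, 0.8)
  expect_equal(met$accuracy, 0.85)
  expect_length(met$undefined, 0)
  perfect <- matrix(c(5, 0, 0, 5), 2, 2)
  met2 <- confusion_metrics(perfect)
  expect_equal(unlist(met2[1:3]), c(sensitivity = 1, specificity = 1,
                                    accuracy = 1))
  no_pos <- matrix(c(5, 0, 2, 0), 2, 2)
  met3 <- confusion_metrics(no_pos)
  expect_true(is.na(met3$sensitivity))
  expect_identical(met3$undefined, "sensitivity")
  expect_error(confusion_metrics(matrix(1, 3, 3)), "2x2")
})
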