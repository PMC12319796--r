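# A small noiseless cohort with a common true rate constant: the fitted model
# must reproduce the observations identically.
fit_noiseless <- local({
  cfg <- cohort_config(cv = 0, k_true = c(median = 68, lo = 68, hi = 68))
  coh <- generate_cohort(n_subjects = 10, seed = 21, config = cfg)
  oefcal(coh)
})

test_that("a noiseless common-k cohort is fitted exactly", {
  fit <- fit_noiseless
  expect_s3_class(fit, "oefcal")
  expect_equal(unname(coef(fit)["k_per_s"]), 68, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["PtO2_mmHg"]), calibrate_pto2(0.6))
  expect_equal(fit$data$oef_mri, fit$data$oef_pet, tolerance = 1e-6)
  expect_true(all(abs(residuals(fit)) < 1e-6))
  for (a in fit$agreement) {
    expect_equal(a$r, 1, tolerance = 1e-6)
    expect_equal(a$bias, 0, tolerance = 1e-7)
  }
})

test_that("fit methods expose the model coherently", {
  fit <- fit_noiseless
  expect_named(coef(fit), c("PtO2_mmHg", "k_per_s"))
  expect_equal(fitted(fit), fit$data$oef_mri)
  # predict on the fitting data reproduces fitted values
  expect_equal(predict(fit), fitted(fit), tolerance = 1e-12)
  # predict with per-subject rates equals cohort rate here (all k equal)
  expect_equal(predict(fit, k = "subject"), fitted(fit), tolerance = 1e-5)
  nd <- data.frame(subject_id = "X", mtt_s = 4.52, cth_s = 5.45)
  expect_equal(predict(fit, nd),
               oef(4.52, 5.45, fit$constants), tolerance = 1e-12)
  expect_output(print(fit), "Calibrated PtO2")
  expect_output(print(summary(fit)), "Bland-Altman")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("per-subject prediction uses each subject's calibrated rate", {
  coh <- generate_cohort(n_subjects = 8, seed = 4,
                         config = cohort_config(cv = 0))
  fit <- oefcal(coh)
  nawm <- fit$data[fit$data$roi == "NAWM", ]
  pred_subj <- predict(fit, nawm, k = "subject")
  # with per-subject k the calibration region is matched exactly
  expect_equal(pred_subj, nawm$oef_pet, tolerance = 1e-5)
  pred_cohort <- predict(fit, nawm, k = "cohort")
  expect_gt(max(abs(pred_cohort - nawm$oef_pet)), 1e-3)
})

test_that("simulate() draws reproducible ceiling-respecting observations", {
  fit <- fit_noiseless
  s1 <- simulate(fit, nsim = 3, seed = 9)
  s2 <- simulate(fit, nsim = 3, seed = 9)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(nrow(fit$data), 3L))
  ceiling_oef <- limit_extraction(fit$constants$PtO2, fit$constants)
  expect_true(all(as.matrix(s1) > 0 & as.matrix(s1) < ceiling_oef))
  # cv = 0 reproduces the fitted values
  s0 <- simulate(fit, seed = 1, cv = 0)
  expect_equal(s0$sim_1, fitted(fit))
})

test_that("estimation-only mode works without PET observations", {
  coh <- generate_cohort(n_subjects = 5, seed = 6)
  coh$oef_pet <- NULL
  cst <- cst_calibrated()
  fit <- oefcal(coh, constants = cst)
  expect_null(fit$calibration)
  expect_length(fit$agreement, 0)
  expect_equal(fitted(fit), oef(coh$mtt_s, coh$cth_s, cst))
  expect_error(residuals(fit), "estimation-only")
  expect_output(print(fit), "Estimation-only")
})
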