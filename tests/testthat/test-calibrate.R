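test_that("tissue tension calibration hits both published anchors", {
  expect_equal(calibrate_pto2(0.6), 21.8, tolerance = 0.2 / 21.8)
  expect_equal(calibrate_pto2(0.5), 25, tolerance = 0.2 / 25)
})

test_that("tissue tension calibration inverts the extraction ceiling exactly", {
  cst <- oef_constants()
  for (target in c(0.05, 0.2, 0.37, 0.6, 0.9))
    expect_equal(limit_extraction(calibrate_pto2(target, cst), cst), target,
                 tolerance = 1e-8)
  # identity in the other direction on feasible tensions
  for (p in c(5, 15, 21.8, 25, 40))
    expect_equal(calibrate_pto2(limit_extraction(p, cst), cst), p,
                 tolerance = 1e-8)
  # zero-extraction limit approaches the arterial-equivalent tension
  P_art <- plasma_tension(cst$S_a * cst$B * (1 - 1e-12), cst)
  expect_equal(calibrate_pto2(1e-9, cst), P_art, tolerance = 1e-4)
  expect_error(calibrate_pto2(0), "infeasible")
  expect_error(calibrate_pto2(1), "infeasible")
})

test_that("rate-constant calibration matches the cohort-level anchor", {
  cst <- oef_constants(PtO2 = calibrate_pto2(0.6))
  k <- calibrate_k(0.37, mtt = 4.52, cth = 5.45, constants = cst)
  expect_true(attr(k, "converged"))
  expect_equal(as.numeric(k), 68, tolerance = 0.10)
})

test_that("rate-constant calibration is a forward-model inverse", {
  cst <- oef_constants(PtO2 = calibrate_pto2(0.6))
  for (k_true in c(5, 68, 100, 400)) {
    ck <- cst; ck$k <- k_true
    target <- oef(4.52, 5.45, ck)
    k_hat <- calibrate_k(target, 4.52, 5.45, cst)
    expect_equal(as.numeric(k_hat), k_true, tolerance = 1e-4)
    # the defining residual of a converged calibration
    ck$k <- as.numeric(k_hat)
    expect_lt(abs(oef(4.52, 5.45, ck) - target), 1e-6)
  }
  ceiling_oef <- limit_extraction(cst$PtO2, cst)
  expect_error(calibrate_k(ceiling_oef + 0.01, 4.52, 5.45, cst),
               "unreachable.*ceiling")
  expect_error(calibrate_k(-0.1, 4.52, 5.45, cst), "target_oef")
})

test_that("OEF increases strictly in k across the whole solver bracket", {
  cst <- oef_constants(PtO2 = calibrate_pto2(0.6))
  ks <- 10^seq(-2, 5, length.out = 40)
  v <- vapply(ks, function(k) { c2 <- cst; c2$k <- k; oef(4.52, 5.45, c2) },
              numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("cohort calibration recovers a shared truth and reports exclusions", {
  cst <- oef_constants()
  # one subject at the cohort-mean inputs collapses to the scalar anchor
  one <- data.frame(subject_id = "S001", roi = "NAWM",
                    mtt_s = 4.52, cth_s = 5.45, oef_pet = 0.37)
  cal1 <- calibrate_cohort(one, target_max_oef = 0.6, constants = cst)
  expect_equal(cal1$k_mean, 68, tolerance = 0.10)
  expect_equal(cal1$pto2, calibrate_pto2(0.6))

  # noiseless forward cohort: every subject's k recovered exactly
  cfg <- cohort_config(cv = 0, rois = cohort_config()$rois["NAWM"])
  coh <- generate_cohort(n_subjects = 10, seed = 3, config = cfg)
  cal <- calibrate_cohort(coh, constants = cst)
  expect_true(all(cal$k$converged))
  k_true <- coh$k_true[match(cal$k$subject_id, coh$subject_id)]
  expect_equal(cal$k$k, k_true, tolerance = 1e-4)
  expect_equal(nrow(cal$excluded), 0L)

  # subjects above the ceiling are excluded with a reason, not dropped
  coh2 <- coh
  coh2$oef_pet[2] <- 0.65
  coh2$oef_pet[5] <- NA_real_
  cal2 <- calibrate_cohort(coh2, constants = cst)
  expect_equal(nrow(cal2$excluded), 2L)
  expect_match(cal2$excluded$reason[cal2$excluded$subject_id ==
                                      coh2$subject_id[2]], "ceiling")
  expect_equal(nrow(cal2$k), 8L)
  expect_false(anyNA(cal2$k_mean))

  expect_error(calibrate_cohort(coh[0, ], constants = cst), "no subjects")
  expect_error(calibrate_cohort(coh[, -3], constants = cst), "mtt_s")
})

test_that("noisy single-seed cohort calibration lands near the true rate", {
  cfg <- cohort_config(cv = 0.10,
                       k_true = c(median = 68, lo = 68, hi = 68))
  coh <- generate_cohort(n_subjects = 68, seed = 1, config = cfg)
  cal <- calibrate_cohort(coh, constants = oef_constants())
  expect_equal(cal$k_mean, 68, tolerance = 0.15)
})
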