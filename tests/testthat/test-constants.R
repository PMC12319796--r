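test_that("Hill saturation has the defining fixed points and monotonicity", {
  cst <- oef_constants()
  expect_identical(hill_saturation(0, cst), 0)
  expect_equal(hill_saturation(cst$P50, cst), 0.5)
  # direct scalar evaluation at twice the half-saturation tension
  expect_equal(hill_saturation(2 * cst$P50, cst), 2^2.8 / (1 + 2^2.8))
  P <- seq(0, 150, by = 0.5)
  expect_true(all(diff(hill_saturation(P, cst)) > 0))
  expect_true(all(hill_saturation(P, cst) < 1))
  expect_error(hill_saturation(-1, cst), ">= 0")
})

test_that("plasma_tension inverts the Hill relation", {
  cst <- oef_constants()
  expect_equal(plasma_tension(cst$B / 2, cst), cst$P50)
  expect_identical(plasma_tension(0, cst), 0)
  expect_equal(plasma_tension(cst$B * hill_saturation(40, cst), cst), 40,
               tolerance = 1e-12)
  # round trip across the open concentration interval
  C <- seq(1e-6, cst$B * (1 - 1e-6), length.out = 200)
  back <- cst$B * hill_saturation(plasma_tension(C, cst), cst)
  expect_equal(back, C, tolerance = 1e-10)
  expect_error(plasma_tension(cst$B, cst), "singularity")
  expect_error(plasma_tension(-0.01, cst), ">= 0")
})

test_that("extraction ceiling matches both published anchor points", {
  cst <- oef_constants()
  expect_equal(limit_extraction(21.8, cst), 0.60, tolerance = 0.01 / 0.60)
  expect_equal(limit_extraction(25, cst), 0.50, tolerance = 0.01 / 0.50)
  # closed-form identity and monotone decrease in tissue tension
  P <- seq(0, 60, by = 0.5)
  expect_equal(limit_extraction(P, cst),
               1 - hill_saturation(P, cst) / cst$S_a)
  expect_true(all(diff(limit_extraction(P, cst)) < 0))
})

test_that("ceiling vanishes when tissue tension reaches the arterial level", {
  cst <- oef_constants()
  P_art <- plasma_tension(cst$S_a * cst$B * (1 - 1e-12), cst)
  expect_lt(limit_extraction(P_art, cst), 1e-8)
  expect_identical(limit_extraction(P_art * 1.5, cst), 0)
  expect_error(limit_extraction(P_art * 1.5, cst, on_no_gradient = "error"),
               "no extraction gradient")
})

test_that("constants are validated and readable from the shipped config", {
  expect_error(oef_constants(P50 = -1), "P50")
  expect_error(oef_constants(S_a = 1.2), "S_a")
  expect_error(oef_constants(k = 0), "k")
  cfg <- system.file("extdata", "constants.yaml", package = "capox")
  cst <- read_constants(cfg)
  expect_s3_class(cst, "oef_constants")
  expect_equal(cst$P50, 26)
  expect_equal(cst$k, 68)
  expect_equal(cst$PtO2, 21.8)
  # partial config falls back to defaults, unknown keys warn
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("PtO2_mmHg: 25", "bogus: 1"), tmp)
  expect_warning(cst2 <- read_constants(tmp), "bogus")
  expect_equal(cst2$PtO2, 25)
  expect_equal(cst2$B, 0.1943)
})
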