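test_that("gamma moment parameterization is the exact closed form", {
  d <- gamma_from_moments(1, 1)
  expect_equal(d$alpha, 1)
  expect_equal(d$beta, 1)
  d <- gamma_from_moments(4.52, 5.45)
  expect_equal(d$alpha, (4.52 / 5.45)^2)
  expect_equal(d$beta, 5.45^2 / 4.52)
  # round trip moments -> (alpha, beta) -> moments
  for (m in c(0.7, 3.4, 4.52)) for (s in c(0.5, 4.08, 9)) {
    mom <- transit_moments(gamma_from_moments(m, s))
    expect_equal(unname(mom), c(m, s))
  }
  expect_error(gamma_from_moments(4.52, 0), "degenerate")
  expect_error(gamma_from_moments(-1, 2), "mtt")
})

test_that("transit-time density is a proper, correctly-shaped pdf", {
  expo <- gamma_from_moments(1, 1)
  expect_equal(gamma_pdf(0, expo), 1)  # exponential density at the origin
  d <- gamma_from_moments(4.52, 5.45)
  q <- qgamma(1 - 1e-10, shape = d$alpha, scale = d$beta)
  expect_equal(integrate(gamma_pdf, 0, q, dist = d,
                         rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
  # mode of a shape-2 gamma sits at (alpha - 1) * beta = 1
  d2 <- structure(list(alpha = 2, beta = 1), class = "transit_dist")
  tau <- seq(0.01, 8, by = 0.01)
  expect_equal(tau[which.max(gamma_pdf(tau, d2))], 1, tolerance = 0.011)
  expect_error(gamma_pdf(-0.1, d2), "tau")
})

test_that("OEF quadrature matches a 1e5-step Riemann oracle over the study box", {
  for (k in c(22, 68, 175)) {
    cst <- cst_calibrated(k = k)
    for (mtt in c(3.14, 4.52, 6.42)) for (cth in c(3.82, 5.45, 8.31)) {
      expect_equal(oef(mtt, cth, cst),
                   oracle_riemann_oef(mtt, cth, cst),
                   tolerance = 1e-4,
                   info = sprintf("mtt=%g cth=%g k=%g", mtt, cth, k))
    }
  }
})

test_that("degenerate heterogeneity collapses OEF to one capillary", {
  cst <- cst_calibrated()
  expect_equal(oef(4.52, 0, cst),
               single_capillary_extraction(4.52, cst), tolerance = 1e-12)
  # small cth approaches the collapse continuously
  expect_equal(oef(4.52, 1e-3, cst),
               single_capillary_extraction(4.52, cst), tolerance = 1e-5)
})

test_that("OEF is ceiling-bounded and monotone as the physiology dictates", {
  cst <- cst_calibrated()
  ceiling_oef <- limit_extraction(cst$PtO2, cst)
  ks <- c(5, 22, 68, 175, 1e3, 1e5)
  v_k <- vapply(ks, function(k) oef(4.52, 5.45, cst_calibrated(k = k)),
                numeric(1))
  expect_true(all(diff(v_k) > 0))          # increasing in k
  expect_true(all(v_k < ceiling_oef))      # below the infinite-k ceiling
  # increasing in mtt at fixed cth/mtt ratio
  m <- seq(1, 10, by = 0.5)
  v_m <- oef(m, 1.2 * m, cst)
  expect_true(all(diff(v_m) > 0))
  # decreasing in cth at fixed mtt over the study parameter box
  for (mtt in c(3.14, 4.52, 6.42)) {
    v_s <- oef(mtt, seq(2.5, 8.5, by = 0.5), cst)
    expect_true(all(diff(v_s) < 0))
  }
})

test_that("quantile truncation of the OEF integral is numerically immaterial", {
  cst <- cst_calibrated()
  # pushing the Riemann truncation far beyond the default 1 - 1e-7 quantile
  near <- oracle_riemann_oef(4.52, 5.45, cst, n = 2e5, p = 1 - 1e-7)
  far <- oracle_riemann_oef(4.52, 5.45, cst, n = 2e5, p = 1 - 1e-12)
  expect_lt(abs(near - far), 1e-5)
  expect_equal(oef(4.52, 5.45, cst), far, tolerance = 1e-4)
})
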