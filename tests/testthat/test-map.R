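test_that("voxelwise OEF map equals elementwise scalar evaluation", {
  cst <- cst_calibrated()
  # uniform maps broadcast the scalar result
  mtt <- array(4.52, c(2, 2, 2))
  cth <- array(5.45, c(2, 2, 2))
  m <- oef_map(mtt, cth, cst)
  expect_equal(as.vector(m), rep(oef(4.52, 5.45, cst), 8), tolerance = 1e-12)
  # random grid matches per-voxel scalar calls
  set.seed(7)
  mtt <- array(runif(8, 2, 7), c(2, 2, 2))
  cth <- array(runif(8, 2, 9), c(2, 2, 2))
  m <- oef_map(mtt, cth, cst)
  ref <- vapply(seq_len(8), function(i) oef(mtt[i], cth[i], cst), numeric(1))
  expect_equal(as.vector(m), ref, tolerance = 1e-6)
})

test_that("mask and invalid voxels propagate as NaN", {
  cst <- cst_calibrated()
  mtt <- array(4.52, c(2, 2, 1))
  cth <- array(5.45, c(2, 2, 1))
  mask <- array(TRUE, c(2, 2, 1)); mask[2, 1, 1] <- FALSE
  m <- oef_map(mtt, cth, cst, mask = mask)
  expect_true(is.nan(m[2, 1, 1]))
  expect_equal(sum(is.nan(m)), 1L)
  # non-finite input inside the mask: NaN plus a warning counting it
  mtt[1, 2, 1] <- NA_real_
  expect_warning(m2 <- oef_map(mtt, cth, cst, mask = mask), "1 in-mask")
  expect_true(is.nan(m2[1, 2, 1]))
  expect_error(oef_map(mtt, array(1, c(3, 1, 1)), cst), "identical shapes")
})

test_that("lookup-grid acceleration stays inside its 1e-3 error budget", {
  cst <- cst_calibrated()
  grid <- oef_lookup(cst, mtt_range = c(2, 8), cth_range = c(2, 9))
  set.seed(11)
  mtt <- runif(50, 2, 8)
  cth <- runif(50, 2, 9)
  exact <- oef(mtt, cth, cst)
  approx <- predict(grid, mtt, cth)
  expect_lt(max(abs(exact - approx)), 1e-3)
  expect_error(predict(grid, 30, 5), "outside")
  # map-level switch agrees with exact evaluation to the same budget
  a_mtt <- array(mtt[1:8], c(2, 2, 2)); a_cth <- array(cth[1:8], c(2, 2, 2))
  expect_lt(max(abs(oef_map(a_mtt, a_cth, cst, lookup = TRUE) -
                    oef_map(a_mtt, a_cth, cst))), 1e-3)
})

test_that("NIfTI maps round-trip with header passthrough", {
  skip_if_not_installed("RNifti")
  cst <- cst_calibrated()
  dir <- withr::local_tempdir()
  mtt <- array(runif(27, 3, 6), c(3, 3, 3))
  cth <- array(runif(27, 3, 8), c(3, 3, 3))
  f_mtt <- file.path(dir, "mtt.nii"); f_cth <- file.path(dir, "cth.nii")
  img <- RNifti::asNifti(mtt, pixdim = c(2, 2, 2))
  RNifti::writeNifti(img, f_mtt)
  RNifti::writeNifti(RNifti::asNifti(cth, pixdim = c(2, 2, 2)), f_cth)
  out <- file.path(dir, "oef.nii")
  oef_nifti(f_mtt, f_cth, out, constants = cst, lookup = FALSE)
  res <- RNifti::readNifti(out)
  expect_equal(dim(res), dim(mtt))
  expect_equal(RNifti::pixdim(res), RNifti::pixdim(img))
  expect_equal(array(as.numeric(res), dim(mtt)), oef_map(mtt, cth, cst),
               tolerance = 1e-6)
})
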