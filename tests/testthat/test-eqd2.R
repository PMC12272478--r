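test_that("EQD2 reproduces the standard worked examples to 2 d.p.", {
  expect_equal(round(eqd2(69, 32, alpha_beta = 2), 2), 71.70)
  expect_equal(round(eqd2(69, 32, alpha_beta = 5), 2), 70.54)
  expect_equal(round(eqd2(69, 32, alpha_beta = 10), 2), 69.90)
})

test_that("2 Gy per fraction is the fixed point for every alpha/beta", {
  for (ab in c(0.5, 1, 2, 3, 10))
    expect_equal(eqd2(60, 30, ab), 60)
  expect_equal(eqd2(44, 22, 1.5), 44)
})

test_that("EQD2 is monotone in alpha/beta with the right sign", {
  # hypofractionated (d > 2): EQD2 exceeds D, decreasing in alpha/beta
  d_hi <- eqd2(60, 20, c(1)) ; d_lo <- eqd2(60, 20, c(10))
  expect_gt(d_hi, 60); expect_gt(d_lo, 60); expect_gt(d_hi, d_lo)
  # hyperfractionated (d < 2): EQD2 below D, increasing in alpha/beta
  expect_lt(eqd2(60, 40, 1), eqd2(60, 40, 10))
  expect_lt(eqd2(60, 40, 10), 60)
})

test_that("large alpha/beta limit recovers the physical dose", {
  expect_equal(eqd2(78, 20, 1e6), 78, tolerance = 1e-3)
})

test_that("EQD2 is vectorized over dose and handles zero", {
  d <- c(0, 10, 50, 80)
  expect_equal(eqd2(d, 32, 2), d * (d / 32 + 2) / 4)
  expect_equal(eqd2(0, 10, 3), 0)
})

test_that("EQD2 validates its inputs", {
  expect_error(eqd2(60, 0, 3), "n_fractions")
  expect_error(eqd2(60, c(10, 20), 3), "n_fractions")
  expect_error(eqd2(60, 30, 0), "alpha_beta")
  expect_error(eqd2(60, 30, -1), "alpha_beta")
  expect_error(eqd2(-5, 30, 3), "non-negative")
})

test_that("eqd2_dsm converts valid voxels and preserves the mask", {
  m <- matrix(60, 91, 90)
  v <- matrix(TRUE, 91, 90); v[1, ] <- FALSE
  m[!v] <- NA
  x <- dsm(m, valid = v, organ = "bladder", dose_kind = "physical")
  y <- eqd2_dsm(x, n_fractions = 20, alpha_beta = 3)
  expect_s3_class(y, "dsm")
  expect_identical(y$valid, v)
  expect_equal(y$doses[2, 1], eqd2(60, 20, 3))
  expect_true(all(is.na(y$doses[1, ])))
  expect_identical(y$dose_kind, "EQD2")
  expect_error(eqd2_dsm(y, 20, 3), "already")
})
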