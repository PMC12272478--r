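# Geometry oracles: the unwrapping code against analytic phantoms with
# closed-form dose fields.

test_that("spherical unwrapping yields the 91 x 90 grid contract", {
  ph <- phantom_sphere_contours(radius = 20, dz = 1)
  g <- uniform_grid(50, lim = 30, h = 2)
  m <- unwrap_bladder_spherical(ph, g)
  expect_s3_class(m, "dsm")
  expect_identical(dim(m$doses), c(91L, 90L))
  expect_identical(length(m$valid), 8190L)
})

test_that("uniform field gives a constant map under both unwrapping modes", {
  g <- uniform_grid(42, lim = 50, h = 2.5)
  mb <- unwrap_bladder_spherical(phantom_sphere_contours(radius = 22, dz = 1), g)
  expect_true(all(mb$valid))
  expect_equal(unname(range(mb$doses)), c(42, 42))
  raw <- unwrap_rectum_cylindrical(phantom_tube_contours(radius = 12,
                                                         length = 80), g)
  mr <- normalize_dsm(raw)
  expect_s3_class(mr, "dsm")
  expect_true(all(mr$valid))
  expect_equal(unname(range(mr$doses)), c(42, 42))
})

test_that("sphere phantom reproduces a radial dose field at relative 1e-3", {
  radius <- 25
  f <- function(z, y, x) 30 + 0.2 * sqrt(z^2 + y^2 + x^2)
  ph <- phantom_sphere_contours(radius, dz = 0.2, n_vertices = 180L)
  g <- field_grid(f, lim = 32, h = 1)
  m <- unwrap_bladder_spherical(ph, g)
  expect_true(all(m$valid))
  expected <- 30 + 0.2 * radius
  expect_lt(max(abs(m$doses / expected - 1)), 1e-3)
})

test_that("rotating a linear dose field shifts bladder map columns", {
  ph <- phantom_sphere_contours(radius = 20, dz = 0.5)
  a <- 4 * pi / 180                      # one column step
  f1 <- function(z, y, x) 60 + 0.3 * x + 0.2 * y
  f2 <- function(z, y, x)
    f1(z, y * cos(a) - x * sin(a), x * cos(a) + y * sin(a))
  m1 <- unwrap_bladder_spherical(ph, field_grid(f1, lim = 28, h = 2))
  m2 <- unwrap_bladder_spherical(ph, field_grid(f2, lim = 28, h = 2))
  shifted <- m1$doses[, c(90, 1:89)]     # column c of m2 = column c-1 of m1
  expect_equal(m2$doses, shifted, tolerance = 1e-8)
})

test_that("rectum map puts an anterior dose gradient at the central columns", {
  ph <- phantom_tube_contours(radius = 12, length = 80)
  g <- field_grid(function(z, y, x) 60 - 0.5 * y, lim = 45, h = 2)
  m <- normalize_dsm(unwrap_rectum_cylindrical(ph, g))
  expect_true(all(m$valid))
  mid <- m$doses[46, ]                   # one interior row
  expect_equal(which.max(mid) %in% 45:46, TRUE)
  expect_true(all(diff(mid[1:45]) > -1e-9))      # rising towards anterior
  expect_true(all(diff(mid[46:90]) < 1e-9))      # falling back to posterior
  expect_equal(mid[45], mid[46], tolerance = 1e-6)
  expect_lt(max(abs(mid - (60 + 0.5 * 12 *
                             cos(((1:90 - 0.5) / 90 * 360 - 180) * pi / 180)))),
            0.05)
})

test_that("normalization is the identity on an already-91-row map", {
  set.seed(4)
  M <- matrix(runif(91 * 90, 20, 70), 91, 90)
  out <- normalize_dsm(M, organ = "rectum")
  expect_equal(out$doses, M, tolerance = 1e-12)
  expect_true(all(out$valid))
})

test_that("normalization preserves constants and monotone columns", {
  M <- matrix(55, 37, 90)
  out <- normalize_dsm(M, organ = "rectum")
  expect_equal(unname(range(out$doses)), c(55, 55))
  Mm <- matrix(seq(10, 70, length.out = 37), 37, 90)
  outm <- normalize_dsm(Mm, organ = "rectum")
  expect_true(all(diff(outm$doses[, 1]) > 0))
  expect_equal(outm$doses[1, 1], 10); expect_equal(outm$doses[91, 1], 70)
})

test_that("normalization marks voxels touching invalid inputs as invalid", {
  M <- matrix(30, 45, 90)
  M[10, 20] <- NA
  out <- normalize_dsm(raw_map(M, is.finite(M), "rectum"))
  expect_false(all(out$valid))
  expect_true(all(is.na(out$doses[!out$valid])))
  expect_equal(sum(out$doses[out$valid] != 30), 0)
})

test_that("exclusion masks reduce validity without touching doses", {
  g <- uniform_grid(42, lim = 30, h = 2.5)
  m <- unwrap_bladder_spherical(phantom_sphere_contours(radius = 18, dz = 1), g)
  mask <- matrix(FALSE, 91, 90); mask[80:91, 40:50] <- TRUE
  m2 <- apply_exclusion_mask(m, mask)
  expect_equal(sum(m2$valid), sum(m$valid) - sum(mask & m$valid))
  expect_true(all(is.na(m2$doses[mask])))
  expect_equal(m2$doses[1, 1], 42)
})

test_that("trilinear interpolation is exact for affine fields", {
  g <- field_grid(function(z, y, x) 20 + 0.1 * z - 0.2 * y + 0.3 * x,
                  lim = 10, h = 2)
  pts <- rbind(c(0.7, -3.1, 2.2), c(-9.9, 9.9, 0), c(0, 0, 0))
  expect_equal(interp_trilinear(g, pts),
               20 + 0.1 * pts[, 1] - 0.2 * pts[, 2] + 0.3 * pts[, 3],
               tolerance = 1e-12)
})

test_that("contour volume matches the closed form for the phantoms", {
  sph <- phantom_sphere_contours(radius = 30, dz = 0.25)
  expect_equal(contour_volume(sph), 4 / 3 * pi * 30^3 / 1000,
               tolerance = 0.01)
  tube <- phantom_tube_contours(radius = 10, length = 100, dz = 1,
                                n_vertices = 360L)
  expect_equal(contour_volume(tube), pi * 10^2 * 100 / 1000,
               tolerance = 0.01)
})

test_that("rays leaving the dose grid are invalidated with a warning", {
  ph <- phantom_sphere_contours(radius = 18, dz = 1)
  g <- uniform_grid(30, lim = 12, h = 2)    # grid too small for the surface
  expect_warning(m <- unwrap_bladder_spherical(ph, g), "invalid")
  expect_s3_class(m, "dsm")
  expect_lt(sum(m$valid), 8190L)
  expect_true(all(is.na(m$doses[!m$valid])))
})
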