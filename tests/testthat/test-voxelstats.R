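# Voxel-wise statistics against hand calculations and the reference
# implementations in stats::t.test / stats::wilcox.test.

test_that("Welch t matches the hand-computed value on a tiny example", {
  ev <- matrix(c(3, 4, 5), 3, 1)
  ne <- matrix(c(1, 2, 3), 3, 1)
  tm <- welch_tmap(ev, ne)
  # means 4 and 2, variances 1 and 1: t = 2 / sqrt(1/3 + 1/3)
  expect_equal(tm$t[1, 1], 2 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tm$n_event, 3L)
  expect_equal(tm$n_nonevent, 3L)
})

test_that("Welch t equals stats::t.test voxel-wise on a 50 vs 50 cohort", {
  set.seed(101)
  V <- 40
  ev <- matrix(rnorm(50 * V, 60, 8), 50, V)
  ne <- matrix(rnorm(50 * V, 57, 11), 50, V)
  tm <- welch_tmap(ev, ne)
  ref <- vapply(seq_len(V), function(j)
    unname(stats::t.test(ev[, j], ne[, j], var.equal = FALSE)$statistic),
    numeric(1))
  expect_lt(max(abs(tm$t[1, ] - ref)), 1e-10)
})

test_that("Mann-Whitney U is exact against stats::wilcox.test", {
  # complete separation, n = 5 each: U takes its maximum 25
  ev <- matrix(c(10, 11, 12, 13, 14), 5, 1)
  ne <- matrix(c(1, 2, 3, 4, 5), 5, 1)
  mw <- mannwhitney_map(ev, ne)
  expect_equal(mw$U[1, 1], 25)
  # random data with ties: raw U matches wilcox.test's W exactly
  set.seed(77)
  V <- 25
  ev <- matrix(sample(40:80, 30 * V, replace = TRUE), 30, V)
  ne <- matrix(sample(35:75, 20 * V, replace = TRUE), 20, V)
  mw <- mannwhitney_map(ev, ne)
  ref <- vapply(seq_len(V), function(j)
    unname(suppressWarnings(
      stats::wilcox.test(ev[, j], ne[, j])$statistic)), numeric(1))
  expect_equal(mw$U[1, ], ref)
  # standardized z has the documented sign: events ranked higher => z > 0
  hi <- mannwhitney_map(matrix(6:10, 5, 1), matrix(1:5, 5, 1))
  expect_gt(hi$t[1, 1], 0)
})

test_that("degenerate voxels are removed from the valid mask, not padded", {
  ev <- cbind(c(5, 5, 5), c(1, 2, 3))
  ne <- cbind(c(5, 5, 5), c(4, 5, 6))
  tm <- welch_tmap(ev, ne)
  expect_false(tm$valid[1, 1])        # zero variance in both groups
  expect_true(is.na(tm$t[1, 1]))
  expect_true(tm$valid[1, 2])
  expect_error(welch_tmap(ev[1:1, , drop = FALSE], ne), "at least 2")
})

test_that("normality screen is calibrated on normal data and fails on skewed", {
  set.seed(55)
  g_norm <- matrix(rnorm(200 * 500), 200, 500)
  sc <- shapiro_screen(g_norm)
  expect_equal(sc$n_tested, 500L)
  # binomial(500, 0.05): 3.5 sigma band around the nominal level
  expect_lt(abs(sc$frac_failing - 0.05), 3.5 * sqrt(0.05 * 0.95 / 500))
  g_exp <- matrix(rexp(200 * 100), 200, 100)
  expect_gt(shapiro_screen(g_exp)$frac_failing, 0.9)
  expect_warning(shapiro_screen(matrix(1:2, 2, 1)), "at least 3")
})

test_that("permutation thresholds use the nearest-rank percentile", {
  set.seed(9)
  X <- matrix(rnorm(40 * 50, 50, 5), 40, 50)
  labels <- rep(c(1, 0), 20)
  pr <- permutation_tmax(X, labels, n_iterations = 200, percentile = 95,
                         seed = 3)
  expect_equal(pr$threshold_upper, sort(pr$tmax_samples)[ceiling(0.95 * 200)])
  expect_equal(pr$threshold_lower, sort(pr$tmin_samples)[ceiling(0.05 * 200)])
  # threshold is monotone in the percentile
  pr99 <- permutation_tmax(X, labels, n_iterations = 200, percentile = 99,
                           seed = 3)
  expect_gte(pr99$threshold_upper, pr$threshold_upper)
  # mask consistency with the reported thresholds
  expect_identical(pr$sig_mask_high,
                   pr$observed$valid & !is.na(pr$observed$t) &
                     pr$observed$t >= pr$threshold_upper)
  expect_identical(pr$sig_mask, pr$sig_mask_high | pr$sig_mask_low)
})

test_that("permutations are seed-reproducible and seed-sensitive", {
  set.seed(12)
  X <- matrix(rnorm(30 * 40, 60, 6), 30, 40)
  labels <- rbinom(30, 1, 0.4); labels[1:2] <- 1; labels[3:4] <- 0
  a <- permutation_tmax(X, labels, n_iterations = 150, seed = 5)
  b <- permutation_tmax(X, labels, n_iterations = 150, seed = 5)
  c <- permutation_tmax(X, labels, n_iterations = 150, seed = 6)
  expect_identical(a$tmax_samples, b$tmax_samples)
  expect_false(identical(a$tmax_samples, c$tmax_samples))
  # observed map does not depend on the permutation seed
  expect_identical(a$observed$t, c$observed$t)
})

test_that("permutation masks keep the 2D map shape", {
  st <- structure(list(X = matrix(rnorm(24 * 8190, 50, 5), 24, 8190),
                       valid = rep(TRUE, 8190), dim = c(91L, 90L),
                       organ = "bladder", dose_kind = "EQD2"),
                  class = "dsm_stack")
  pr <- permutation_tmax(st, rep(c(1, 0), 12), n_iterations = 100, seed = 2)
  expect_identical(dim(pr$sig_mask), c(91L, 90L))
  expect_identical(dim(pr$observed$t), c(91L, 90L))
})

test_that("labels with NA are excluded before permuting", {
  set.seed(8)
  X <- matrix(rnorm(20 * 30), 20, 30)
  labels <- c(rep(1, 8), rep(0, 8), rep(NA, 4))
  pr <- permutation_tmax(X, labels, n_iterations = 100, seed = 1)
  expect_equal(pr$observed$n_event, 8L)
  expect_equal(pr$observed$n_nonevent, 8L)
  expect_error(permutation_tmax(X, c(rep(1, 19), 0), n_iterations = 100),
               "at least 2")
})

test_that("DSC has the defining properties", {
  A <- matrix(FALSE, 91, 90); B <- matrix(FALSE, 91, 90)
  expect_equal(dsc(A, B)$dsc, 0)                 # empty vs empty
  A[1:10, 1:10] <- TRUE
  expect_equal(dsc(A, A)$dsc, 1)                 # identity
  expect_equal(dsc(A, B)$dsc, 0)                 # disjoint (B empty)
  B[50:60, 50:60] <- TRUE
  expect_equal(dsc(A, B)$dsc, 0)                 # disjoint non-empty
  expect_equal(dsc(A, B)$dsc, dsc(B, A)$dsc)     # symmetry
  # nested masks of sizes 1143 and 186 overlap completely:
  # 2 * 186 / (1143 + 186) = 0.2799...
  A2 <- matrix(FALSE, 91, 90); A2[seq_len(1143)] <- TRUE
  B2 <- matrix(FALSE, 91, 90); B2[seq_len(186)] <- TRUE
  expect_equal(round(dsc(A2, B2)$dsc, 2), 0.28)
  expect_error(dsc(A2, matrix(FALSE, 2, 2)), "identical shape")
})

test_that("count_significant counts and bounds", {
  m <- matrix(FALSE, 91, 90); m[3, 7] <- TRUE; m[90, 90] <- TRUE
  expect_equal(count_significant(m), 2L)
  expect_lte(count_significant(m), 8190L)
  expect_error(count_significant(matrix(1, 2, 2)))
})
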