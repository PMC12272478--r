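test_that("worked examples of both dichotomization rules", {
  g <- grade_table(list(
    c(1, 2, 1),    # follow-up above baseline: event under both methods
    c(1, 1, 1),    # at baseline level: event only uncorrected
    c(2, 1, 0),    # below baseline: event only uncorrected
    c(0, 0, 0),    # never toxic: no event either way
    c(0, 0, 2),    # late event: event under both
    c(3, 3, 3)))   # severe but unchanged: corrected non-event
  u <- dichotomize_uncorrected(g)
  co <- dichotomize_corrected(g)
  expect_equal(u$event, c(1L, 1L, 1L, 0L, 1L, 1L))
  expect_equal(co$event, c(1L, 0L, 0L, 0L, 1L, 0L))
  expect_false(any(u$excluded) || any(co$excluded))
})

test_that("cutpoint shifts the event threshold", {
  g <- grade_table(list(c(0, 1, 1), c(0, 2, 1), c(1, 3, 0)))
  expect_equal(dichotomize_uncorrected(g, cutpoint = 2)$event, c(0L, 1L, 1L))
  expect_equal(dichotomize_corrected(g, cutpoint = 2)$event, c(0L, 1L, 1L))
})

test_that("missing time points are handled, not dropped", {
  g <- grade_table(list(
    c(0, NA, 2),   # single follow-up carries the label
    c(0, 1, NA),
    c(0, NA, NA),  # no follow-up at all: excluded
    c(NA, 2, 0)))  # missing baseline: only the corrected method excludes
  u <- dichotomize_uncorrected(g)
  co <- dichotomize_corrected(g)
  expect_equal(u$event, c(1L, 1L, NA_integer_, 1L))
  expect_equal(u$excluded, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(co$event, c(1L, 1L, NA_integer_, NA_integer_))
  expect_equal(co$excluded, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(nrow(u), 4L)        # every patient accounted for
})

test_that("corrected events are a subset of uncorrected events", {
  g <- grade_table(random_triples(10000, seed = 31))
  u <- dichotomize_uncorrected(g)
  co <- dichotomize_corrected(g)
  both <- !u$excluded & !co$excluded
  expect_true(all(co$event[both] <= u$event[both]))
  # exclusion is one-directional too: uncorrected-excluded implies
  # corrected-excluded
  expect_true(all(co$excluded[u$excluded]))
})

test_that("grades outside 0..3 are refused", {
  g <- grade_table(list(c(0, 4, 0)))
  expect_error(dichotomize_uncorrected(g), "0..3")
  g2 <- grade_table(list(c(-1, 0, 0)))
  expect_error(dichotomize_corrected(g2), "0..3")
  expect_error(dichotomize_uncorrected(data.frame(x = 1)), "columns")
})

test_that("dichotomize() dispatches on the method name", {
  g <- grade_table(list(c(1, 1, 0), c(0, 2, 0)))
  expect_identical(dichotomize(g, "uncorrected"),
                   dichotomize_uncorrected(g))
  expect_identical(dichotomize(g, "baseline_corrected"),
                   dichotomize_corrected(g))
  expect_error(dichotomize(g, "other"))
})

test_that("split_cohort partitions patients and counts exclusions", {
  X <- matrix(seq_len(5 * 8190), 5, 8190)
  st <- X                              # plain patient-by-voxel matrix
  labels <- c(1, 0, NA, 1, 0)
  sp <- suppressWarnings(split_cohort(st, labels))
  expect_equal(nrow(sp$event), 2L)
  expect_equal(nrow(sp$nonevent), 2L)
  expect_equal(sp$n_excluded, 1L)
  expect_equal(sp$event[1, 1], X[1, 1])
  expect_equal(sp$nonevent[2, 1], X[5, 1])
  expect_warning(split_cohort(st, c(1, 0, 0, 0, 0)), "fewer than 2")
  expect_error(split_cohort(st, c(1, 0)), "one label per patient")
})
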