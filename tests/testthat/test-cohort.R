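# Synthetic cohort generator: determinism, population statistics, and
# the toxicity link.

test_that("cohort specs validate their inputs", {
  expect_error(cohort_spec(n_patients = 1), "at least 2")
  expect_error(cohort_spec(organ = "prostate"))
  expect_error(cohort_spec(planted_region = matrix(TRUE, 3, 3)), "91 x 90")
  ok <- cohort_spec(planted_region = cbind(5:10, 7:12))   # index form
  expect_true(is.logical(ok$planted_region))
  expect_equal(sum(ok$planted_region), 6)
})

test_that("default planted regions are plausible organ subregions", {
  for (organ in c("bladder", "rectum")) {
    pr <- default_planted_region(organ)
    expect_identical(dim(pr), c(91L, 90L))
    expect_gt(sum(pr), 100)
    expect_lt(sum(pr), 2000)
  }
  expect_false(identical(default_planted_region("bladder"),
                         default_planted_region("rectum")))
})

test_that("derived seeds are deterministic, distinct and below 2^31", {
  s1 <- patient_seed(1L, 1, 0)
  expect_identical(s1, patient_seed(1L, 1, 0))
  expect_false(s1 == patient_seed(1L, 2, 0))
  expect_false(s1 == patient_seed(1L, 1, 1))
  extremes <- c(patient_seed(.Machine$integer.max, 10000, 9),
                patient_seed(0, 1, 0), patient_seed(123456789, 400, 3))
  expect_true(all(extremes >= 0 & extremes < 2^31))
})

test_that("cohort generation is seed-reproducible", {
  sp <- cohort_spec(n_patients = 4, seed = 7)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a$stack$X, b$stack$X)
  expect_identical(a$grades, b$grades)
  c <- generate_cohort(cohort_spec(n_patients = 4, seed = 8))
  expect_false(identical(a$stack$X, c$stack$X))
})

test_that("generated bladder volumes match the population target", {
  sp <- cohort_spec(n_patients = 1000, seed = 21)
  vols <- vapply(seq_len(1000), function(i)
    contour_volume(generate_organ_geometry(sp, i)), numeric(1))
  expect_lt(abs(mean(vols) / 162.9 - 1), 0.10)
  expect_gt(stats::sd(vols), 50)      # heavy population spread, lognormal
  expect_true(all(vols > 0))
})

test_that("generated rectum dimensions match the population target", {
  sp <- cohort_spec(n_patients = 300, organ = "rectum", seed = 22)
  vols <- numeric(300); lens <- numeric(300)
  for (i in seq_len(300)) {
    cont <- generate_organ_geometry(sp, i)
    vols[i] <- contour_volume(cont)
    zr <- range(vapply(cont$slices, function(s) s$z, numeric(1)))
    lens[i] <- diff(zr)
  }
  expect_lt(abs(mean(vols) / 68.4 - 1), 0.15)
  expect_lt(abs(mean(lens) / 97 - 1), 0.10)
})

test_that("dose grids are physical and scale with the prescription", {
  sp <- cohort_spec(n_patients = 3, seed = 5)
  for (i in 1:3) {
    cont <- generate_organ_geometry(sp, i)
    pd <- generate_dose(sp, cont, patient_index = i)
    expect_s3_class(pd$grid, "dose_grid")
    expect_true(all(pd$grid$values >= 0))
    expect_lt(max(pd$grid$values), 1.5 * pd$prescription)
    expect_gte(pd$n_fractions, 1)
  }
})

test_that("the logistic link hits its nominal event rate when flat", {
  sp <- cohort_spec(n_patients = 2, intercept = stats::qlogis(0.3),
                    effect_size = 0, baseline_prevalence = 0, seed = 99)
  flat <- matrix(50, 91, 90)
  events <- vapply(seq_len(10000), function(i) {
    r <- generate_toxicity(sp, flat, patient_index = i)$records
    as.integer(max(r$grade_12m, r$grade_24m) >= 1)
  }, integer(1))
  expect_lt(abs(mean(events) - 0.30), 0.015)
})

test_that("baseline prevalence 1 gives every patient baseline toxicity", {
  sp <- cohort_spec(n_patients = 2, baseline_prevalence = 1, seed = 3)
  flat <- matrix(50, 91, 90)
  base <- vapply(1:200, function(i)
    generate_toxicity(sp, flat, patient_index = i)$records$grade_baseline,
    integer(1))
  expect_true(all(base == 1L))
})

test_that("grades stay in domain and encode the event correctly", {
  sp <- cohort_spec(n_patients = 40, seed = 13)
  co <- generate_cohort(sp)
  g <- co$grades
  expect_true(all(unlist(g[c("grade_baseline", "grade_12m", "grade_24m")])
                  %in% 0:3))
  expect_equal(nrow(g), 40L * length(sp$endpoints))
  # truth probabilities are probabilities
  expect_true(all(co$meta$truth_event_probability >= 0 &
                    co$meta$truth_event_probability <= 1))
  expect_identical(dim(co$stack$X), c(40L, 8190L))
  expect_identical(co$stack$dose_kind, "EQD2")
})

test_that("null-cohort simulator is reproducible with balanced groups", {
  a <- simulate_null_cohort(n_patients = 30, seed = 4)
  b <- simulate_null_cohort(n_patients = 30, seed = 4)
  expect_identical(a$X, b$X); expect_identical(a$labels, b$labels)
  expect_identical(a$dim, c(20L, 20L))
  expect_identical(dim(a$X), c(30L, 400L))
  expect_gte(sum(a$labels), 2L)
  expect_gte(sum(1 - a$labels), 2L)
  c <- simulate_null_cohort(n_patients = 30, seed = 5)
  expect_false(identical(a$X, c$X))
})
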