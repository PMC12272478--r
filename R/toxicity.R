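# Toxicity grade handling: dichotomization with and without baseline
# correction, and splitting of dose-surface maps by outcome label.
#
# Grades are CTCAE-style integers 0-3 recorded at baseline, 12 and 24
# months. Both labelling methods take the maximum of the follow-up grades
# and dichotomize at a cutpoint (grade >= 1 by default); the corrected
# method first subtracts the baseline grade, so a patient whose follow-up
# severity does not exceed the pre-treatment level is a non-event.

check_grades <- function(g, what) {
  bad <- !is.na(g) & !(g %in% 0:3)
  if (any(bad)) stop(sprintf("%s grades must be integers in 0..3 or NA", what))
}

as_grade_table <- function(grades) {
  need <- c("patient_id", "endpoint", "grade_baseline", "grade_12m", "grade_24m")
  if (!is.data.frame(grades) || !all(need %in% names(grades)))
    stop("`grades` must be a data frame with columns ",
         paste(need, collapse = ", "))
  for (cn in need[3:5]) check_grades(grades[[cn]], cn)
  grades
}

#' Dichotomize toxicity grades without baseline correction
#'
#' A patient is an event when the maximum follow-up grade (over the 12-
#' and 24-month assessments, ignoring missing time points) reaches the
#' cutpoint. The baseline grade plays no role. Patients with both
#' follow-ups missing cannot be labelled and are flagged as excluded,
#' never silently dropped.
#'
#' @param grades Data frame with columns `patient_id`, `endpoint`,
#'   `grade_baseline`, `grade_12m`, `grade_24m` (integer 0-3 or NA).
#' @param cutpoint Event threshold on the (adjusted) grade; default 1.
#' @return Data frame with columns `patient_id`, `endpoint`, `method`,
#'   `event` (0/1, NA when excluded) and `excluded` (logical).
#' @export
dichotomize_uncorrected <- function(grades, cutpoint = 1L) {
  grades <- as_grade_table(grades)
  fu <- pmax(ifelse(is.na(grades$grade_12m), -Inf, grades$grade_12m),
             ifelse(is.na(grades$grade_24m), -Inf, grades$grade_24m))
  excluded <- !is.finite(fu)
  event <- ifelse(excluded, NA_integer_, as.integer(fu >= cutpoint))
  data.frame(patient_id = grades$patient_id, endpoint = grades$endpoint,
             method = "uncorrected", event = event, excluded = excluded,
             stringsAsFactors = FALSE)
}

#' Dichotomize toxicity grades with baseline correction
#'
#' The baseline grade is subtracted from the maximum follow-up grade
#' before dichotomizing, so only an increase over the pre-treatment
#' severity counts as an event. Negative adjusted grades (follow-up below
#' baseline) map to non-event. Patients missing the baseline grade, or
#' both follow-ups, are flagged as excluded under this method.
#'
#' @inheritParams dichotomize_uncorrected
#' @return Data frame as in [dichotomize_uncorrected()] with
#'   `method = "baseline_corrected"`.
#' @export
dichotomize_corrected <- function(grades, cutpoint = 1L) {
  grades <- as_grade_table(grades)
  fu <- pmax(ifelse(is.na(grades$grade_12m), -Inf, grades$grade_12m),
             ifelse(is.na(grades$grade_24m), -Inf, grades$grade_24m))
  excluded <- !is.finite(fu) | is.na(grades$grade_baseline)
  adj <- fu - grades$grade_baseline
  event <- ifelse(excluded, NA_integer_, as.integer(adj >= cutpoint))
  data.frame(patient_id = grades$patient_id, endpoint = grades$endpoint,
             method = "baseline_corrected", event = event, excluded = excluded,
             stringsAsFactors = FALSE)
}

#' Dichotomize by method name
#'
#' @inheritParams dichotomize_uncorrected
#' @param method `"uncorrected"` or `"baseline_corrected"`.
#' @return See [dichotomize_uncorrected()].
#' @export
dichotomize <- function(grades, method = c("uncorrected", "baseline_corrected"),
                        cutpoint = 1L) {
  switch(match.arg(method),
         uncorrected = dichotomize_uncorrected(grades, cutpoint),
         baseline_corrected = dichotomize_corrected(grades, cutpoint))
}

#' Split dose-surface maps into event and non-event groups
#'
#' Partitions a patient-by-voxel stack by binary outcome label. Excluded
#' patients (label `NA`) are removed from both groups and counted.
#'
#' @param stack A [dsm_stack()] (or list of [dsm()] / matrix) with one
#'   row per patient, ordered as `labels`.
#' @param labels Data frame from a dichotomization function, or a plain
#'   0/1 vector, one entry per stack row.
#' @return List with `event` and `nonevent` matrices (patients x voxels),
#'   `valid` mask, `n_event`, `n_nonevent`, `n_excluded`.
#' @export
split_cohort <- function(stack, labels) {
  stack <- as_stack(stack)
  ev <- if (is.data.frame(labels)) labels$event else labels
  if (length(ev) != nrow(stack$X))
    stop("need exactly one label per patient row")
  keep <- !is.na(ev)
  groups <- list(event = stack$X[keep & ev == 1, , drop = FALSE],
                 nonevent = stack$X[keep & ev == 0, , drop = FALSE],
                 valid = stack$valid,
                 n_event = sum(ev == 1, na.rm = TRUE),
                 n_nonevent = sum(ev == 0, na.rm = TRUE),
                 n_excluded = sum(!keep))
  if (groups$n_event < 2L || groups$n_nonevent < 2L)
    warning("a group has fewer than 2 patients; voxel-wise statistics will refuse this split")
  groups
}
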