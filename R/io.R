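# Plain-text I/O for dose-surface maps, toxicity tables and cohort
# bundles. Everything is CSV/JSON so bundles are portable and diffable;
# a cohort bundle is a directory with a JSON sidecar echoing the spec,
# one DSM CSV per patient, and the cohort toxicity table.

#' Write a dose-surface map as CSV plus JSON metadata
#'
#' The CSV holds 91 data rows by 90 columns (header row of phi/column
#' indices); invalid voxels are written as empty fields. Organ, dose kind
#' and a run-length encoding of the validity mask go to a JSON sidecar
#' `<path>.json`.
#'
#' @param x A [dsm()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dsm_csv <- function(x, path) {
  stopifnot(inherits(x, "dsm"))
  df <- as.data.frame(x$doses)
  names(df) <- sprintf("c%02d", seq_len(ncol(df)))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  rle_v <- rle(as.vector(x$valid))
  meta <- list(organ = x$organ, dose_kind = x$dose_kind,
               valid_rle = list(lengths = rle_v$lengths,
                                values = rle_v$values))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a dose-surface map written by [write_dsm_csv()]
#'
#' @param path CSV path (the JSON sidecar `<path>.json` must exist).
#' @return A [dsm()].
#' @export
read_dsm_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path))
  dimnames(m) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  valid <- matrix(inverse.rle(list(lengths = meta$valid_rle$lengths,
                                   values = meta$valid_rle$values)),
                  nrow(m), ncol(m))
  dsm(m, valid = valid, organ = meta$organ, dose_kind = meta$dose_kind)
}

#' Write a cohort bundle to a directory
#'
#' Layout: `spec.json` (generator spec or provenance echo),
#' `toxicity.csv` (patient_id, endpoint, grade_baseline, grade_12m,
#' grade_24m), `meta.csv` (per-patient prescription and fractionation),
#' and `dsm/patient_<i>.csv` per patient.
#'
#' @param cohort A `drm_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_bundle <- function(cohort, dir) {
  stopifnot(inherits(cohort, "drm_cohort"))
  dir.create(file.path(dir, "dsm"), recursive = TRUE, showWarnings = FALSE)
  sp <- cohort$spec
  sp_json <- sp
  sp_json$planted_region <- which(sp$planted_region, arr.ind = TRUE)
  class(sp_json) <- NULL
  jsonlite::write_json(sp_json, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(cohort$grades, file.path(dir, "toxicity.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$meta, file.path(dir, "meta.csv"), row.names = FALSE)
  n <- nrow(cohort$stack$X)
  for (i in seq_len(n)) {
    m <- matrix(cohort$stack$X[i, ], cohort$stack$dim[1], cohort$stack$dim[2])
    v <- matrix(cohort$stack$valid, cohort$stack$dim[1], cohort$stack$dim[2])
    d <- dsm(m, valid = v & is.finite(m), organ = cohort$stack$organ,
             dose_kind = cohort$stack$dose_kind)
    write_dsm_csv(d, file.path(dir, "dsm", sprintf("patient_%04d.csv", i)))
  }
  invisible(dir)
}

#' Read a cohort bundle written by [write_cohort_bundle()]
#'
#' @param dir Bundle directory.
#' @return A `drm_cohort` (without raw per-patient geometry).
#' @export
read_cohort_bundle <- function(dir) {
  spj <- jsonlite::read_json(file.path(dir, "spec.json"),
                             simplifyVector = TRUE)
  spec <- cohort_spec(n_patients = spj$n_patients,
                      prescription_dose = spj$prescription_dose,
                      prescription_sd = spj$prescription_sd,
                      n_fractions = spj$n_fractions,
                      fractions_sd = spj$fractions_sd,
                      organ = spj$organ,
                      planted_region = as.matrix(spj$planted_region),
                      effect_size = spj$effect_size,
                      dose_ref = spj$dose_ref, intercept = spj$intercept,
                      baseline_prevalence = spj$baseline_prevalence,
                      baseline_boost = spj$baseline_boost,
                      grade_noise = spj$grade_noise,
                      endpoints = spj$endpoints, seed = spj$seed)
  files <- sort(list.files(file.path(dir, "dsm"), pattern = "\\.csv$",
                           full.names = TRUE))
  dsms <- lapply(files, read_dsm_csv)
  structure(list(stack = dsm_stack(dsms),
                 grades = utils::read.csv(file.path(dir, "toxicity.csv"),
                                          stringsAsFactors = FALSE),
                 meta = utils::read.csv(file.path(dir, "meta.csv")),
                 spec = spec, patients = NULL),
            class = "drm_cohort")
}
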