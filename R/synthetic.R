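# Synthetic cohort generation: organ geometry, dose fields and toxicity
# outcomes with a known planted dose-response subregion, so the whole
# pipeline can be exercised and validated without clinical data.
#
# Study conditions emulated (cohort means, per-patient variation):
# prescription 71.4 +/- 6.7 Gy in 33.8 +/- 6.7 fractions; bladder volume
# 162.9 +/- 123.8 cm^3; rectum volume 68.4 +/- 23.5 cm^3, length
# 9.7 +/- 1.3 cm. Toxicity events follow a logistic link on the mean
# EQD2 dose over a planted surface subregion, plus a baseline-toxicity
# prevalence component.

#' Specification of a synthetic cohort
#'
#' Collects every parameter of the generator in one validated object.
#' Identical specs (including `seed`) produce bit-identical cohorts; each
#' patient draws from a pseudo-random stream derived from
#' `(seed, patient_index)` so cohorts are reproducible regardless of
#' generation order.
#'
#' @param n_patients Number of patients (>= 2).
#' @param prescription_dose Cohort mean prescribed dose in Gy (> 0).
#' @param prescription_sd Between-patient SD of the prescribed dose (Gy).
#' @param n_fractions Cohort mean fraction count (>= 1).
#' @param fractions_sd Between-patient SD of the fraction count.
#' @param organ `"bladder"` or `"rectum"`.
#' @param planted_region Logical 91 x 90 matrix (or 2-column index matrix
#'   of rows/cols) marking the surface subregion whose mean dose drives
#'   toxicity. Default: [default_planted_region()] for the organ.
#' @param effect_size Log-odds of a toxicity event per Gy of planted-
#'   region dose excess (regional mean EQD2 minus the patient's
#'   whole-map mean, centred at `dose_ref`).
#' @param dose_ref Centring excess dose (Gy) for the logistic link, so
#'   the marginal event rate stays near `plogis(intercept)` whatever the
#'   effect size. The default matches the typical planted-region excess
#'   under the default geometry and dose model.
#' @param intercept Logistic intercept; default `qlogis(0.4)` targets a
#'   40 percent marginal event rate.
#' @param baseline_prevalence Probability of a grade >= 1 baseline
#'   toxicity, in `[0, 1]`.
#' @param baseline_boost Additional log-odds of a follow-up event for
#'   patients with baseline toxicity (their confounding component).
#' @param grade_noise Probabilities of maximum follow-up grades 1, 2, 3
#'   given an event (normalized internally).
#' @param endpoints Character vector of endpoint names to generate.
#' @param seed Integer master seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 400L,
                        prescription_dose = 71.4, prescription_sd = 6.7,
                        n_fractions = 34L, fractions_sd = 6.7,
                        organ = c("bladder", "rectum"),
                        planted_region = NULL,
                        effect_size = 0.06,
                        dose_ref = 43,
                        intercept = stats::qlogis(0.4),
                        baseline_prevalence = 0.2,
                        baseline_boost = 1.0,
                        grade_noise = c(0.65, 0.25, 0.10),
                        endpoints = "urinary_incontinence",
                        seed = 1L) {
  organ <- match.arg(organ)
  if (n_patients < 2L) stop("`n_patients` must be at least 2")
  if (prescription_dose <= 0) stop("`prescription_dose` must be positive")
  if (n_fractions < 1L) stop("`n_fractions` must be at least 1")
  if (baseline_prevalence < 0 || baseline_prevalence > 1)
    stop("`baseline_prevalence` must be in [0, 1]")
  if (length(grade_noise) != 3L || any(grade_noise < 0) || sum(grade_noise) <= 0)
    stop("`grade_noise` must be 3 non-negative grade probabilities")
  if (is.null(planted_region)) planted_region <- default_planted_region(organ)
  if (is.matrix(planted_region) && !is.logical(planted_region)) {
    m <- matrix(FALSE, DSM_ROWS, DSM_COLS)
    m[planted_region] <- TRUE
    planted_region <- m
  }
  if (!is.logical(planted_region) ||
      !all(dim(planted_region) == c(DSM_ROWS, DSM_COLS)))
    stop("`planted_region` must be logical 91 x 90 or an index matrix within it")
  if (!any(planted_region)) stop("`planted_region` must be non-empty")
  structure(list(n_patients = as.integer(n_patients),
                 prescription_dose = prescription_dose,
                 prescription_sd = prescription_sd,
                 n_fractions = as.integer(n_fractions),
                 fractions_sd = fractions_sd, organ = organ,
                 planted_region = planted_region,
                 effect_size = effect_size, dose_ref = dose_ref,
                 intercept = intercept,
                 baseline_prevalence = baseline_prevalence,
                 baseline_boost = baseline_boost,
                 grade_noise = grade_noise / sum(grade_noise),
                 endpoints = endpoints,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> %d patients, %s, %.1f Gy / %d fractions\n",
                     "  planted region: %d voxels, effect %.3f logit/Gy, ",
                     "baseline prevalence %.2f, seed %d\n"),
              x$n_patients, x$organ, x$prescription_dose, x$n_fractions,
              sum(x$planted_region), x$effect_size, x$baseline_prevalence,
              x$seed))
  invisible(x)
}

#' Default planted high-risk subregion
#'
#' A rectangular block of surface voxels sitting in the high-dose area of
#' the default dose field: for the bladder, the infero-posterior wall
#' facing the prostate-like target (rows 60-78, columns straddling
#' posterior); for the rectum, the anterior wall at mid-organ height.
#'
#' @param organ `"bladder"` or `"rectum"`.
#' @return Logical 91 x 90 matrix.
#' @export
default_planted_region <- function(organ = c("bladder", "rectum")) {
  organ <- match.arg(organ)
  m <- matrix(FALSE, DSM_ROWS, DSM_COLS)
  if (organ == "bladder") {
    m[60:78, 38:54] <- TRUE       # infero-posterior wall
  } else {
    m[36:56, 38:53] <- TRUE       # anterior wall, mid-height
  }
  m
}

#' Deterministic derived seed
#'
#' Derives an integer seed for one patient (or analysis) and pipeline
#' stage from a master seed, so independent stages never share an RNG
#' stream. The result is always in `[0, 2147483628]`, a valid
#' `set.seed()` argument on every platform.
#'
#' @param seed Master seed (integer).
#' @param patient_index Patient or analysis number (1-based).
#' @param stage Stage discriminator (0 geometry, 1 dose, 2 toxicity;
#'   other values free for callers).
#' @return One numeric seed below 2^31.
#' @export
patient_seed <- function(seed, patient_index, stage = 0L) {
  ((as.double(seed) %% 65011) * 33013 + patient_index * 101 + stage) %% 2147483629
}

# ---- geometry ------------------------------------------------------------

#' Generate one patient's organ contours
#'
#' Bladder: an ellipsoid with per-patient random semi-axes whose enclosed
#' volume follows a log-normal law matching the target 162.9 +/- 123.8
#' cm^3 distribution, perturbed by smooth low-order angular harmonics
#' (kept star-shaped about each slice centroid). Rectum: a gently curved
#' near-circular tube, length drawn around 9.7 +/- 1.3 cm and cross-
#' section scaled so the enclosed volume matches 68.4 +/- 23.5 cm^3.
#' Polygons are closed, simple, and have at least 24 vertices per slice.
#'
#' @param spec A [cohort_spec()].
#' @param patient_index Patient number within the cohort (1-based).
#' @param n_vertices Vertices per slice polygon (default 48).
#' @param dz Slice spacing in mm (default 2.5).
#' @return [organ_contours()] with a `patient_index` attribute.
#' @export
generate_organ_geometry <- function(spec, patient_index, n_vertices = 48L,
                                    dz = 2.5) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (n_vertices < 24L) stop("at least 24 vertices per slice required")
  set.seed(patient_seed(spec$seed, patient_index, 0L))
  cont <- if (spec$organ == "bladder") {
    gen_bladder_contours(n_vertices, dz)
  } else {
    gen_rectum_contours(n_vertices, dz)
  }
  attr(cont, "patient_index") <- patient_index
  cont
}

# log-normal with given mean and sd on the natural scale
rlnorm_msd <- function(n, m, s) {
  sig2 <- log(1 + (s / m)^2)
  stats::rlnorm(n, meanlog = log(m) - sig2 / 2, sdlog = sqrt(sig2))
}

gen_bladder_contours <- function(n_vertices, dz) {
  vol <- rlnorm_msd(1, 162.9, 123.8) * 1000        # mm^3
  # random aspect ratios around 1, then scale to the drawn volume
  asp <- exp(stats::rnorm(3, 0, 0.12))
  s <- (vol / (4 / 3 * pi * prod(asp)))^(1 / 3)
  ax <- asp * s                                     # (a_x, b_y, c_z) mm
  # low-order angular perturbation, constant over z: star-shaped, simple
  amp <- stats::runif(2, 0, 0.05)
  phase <- stats::runif(2, 0, 2 * pi)
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  pert <- 1 + amp[1] * cos(2 * ang + phase[1]) + amp[2] * cos(3 * ang + phase[2])
  zs <- seq(-ax[3] + dz / 2, ax[3] - dz / 2, by = dz)
  slices <- lapply(zs, function(z) {
    f <- sqrt(max(0, 1 - (z / ax[3])^2))
    x <- ax[1] * f * pert * cos(ang)
    y <- ax[2] * f * pert * sin(ang)
    list(z = z, vertices = cbind(y, x))
  })
  organ_contours(slices, "bladder")
}

gen_rectum_contours <- function(n_vertices, dz) {
  len <- max(40, stats::rnorm(1, 97, 13))           # mm
  vol <- rlnorm_msd(1, 68.4, 23.5) * 1000           # mm^3
  r0 <- sqrt(vol / (pi * len))                      # mean cross-section radius
  zs <- seq(-len / 2, len / 2, by = dz)
  # gentle anterior bowing of the centreline plus smooth radius variation
  bow <- stats::runif(1, 3, 10)
  rad_amp <- stats::runif(1, 0, 0.1)
  rad_ph <- stats::runif(1, 0, 2 * pi)
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  ecc <- exp(stats::rnorm(1, 0, 0.08))              # slight slice ellipticity
  slices <- lapply(zs, function(z) {
    u <- z / (len / 2)
    cy <- -bow * (1 - u^2)                          # bow towards anterior (-y)
    rk <- r0 * (1 + rad_amp * sin(2 * pi * (u + 1) / 2 + rad_ph))
    x <- rk * ecc * cos(ang)
    y <- cy + rk / ecc * sin(ang)
    list(z = z, vertices = cbind(y, x))
  })
  organ_contours(slices, "rectum")
}

#' Analytic sphere phantom contours
#'
#' Slice polygons of a perfect sphere, for oracle tests of the spherical
#' unwrapping (every surface sample lies at radius `radius` from
#' `centre`).
#'
#' @param radius Sphere radius in mm.
#' @param centre Numeric (z, y, x) centre in mm.
#' @param dz Slice spacing in mm.
#' @param n_vertices Vertices per slice.
#' @param organ Organ label carried by the contours.
#' @return [organ_contours()].
#' @export
phantom_sphere_contours <- function(radius, centre = c(0, 0, 0), dz = 1,
                                    n_vertices = 180L,
                                    organ = "bladder") {
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  zs <- seq(-radius + dz / 2, radius - dz / 2, by = dz)
  slices <- lapply(zs, function(zrel) {
    r <- sqrt(max(0, radius^2 - zrel^2))
    list(z = centre[1] + zrel,
         vertices = cbind(centre[2] + r * sin(ang), centre[3] + r * cos(ang)))
  })
  organ_contours(slices, organ)
}

#' Analytic straight-tube phantom contours
#'
#' Circular-slice cylinder for oracle tests of the cylindrical
#' unwrapping.
#'
#' @param radius Tube radius in mm.
#' @param length Tube length in mm.
#' @param centre Numeric (z, y, x) of the tube midpoint.
#' @param dz Slice spacing in mm.
#' @param n_vertices Vertices per slice.
#' @return [organ_contours()] labelled `"rectum"`.
#' @export
phantom_tube_contours <- function(radius, length, centre = c(0, 0, 0),
                                  dz = 2.5, n_vertices = 90L) {
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  zs <- seq(-length / 2, length / 2, by = dz)
  slices <- lapply(zs, function(zrel) {
    list(z = centre[1] + zrel,
         vertices = cbind(centre[2] + radius * sin(ang),
                          centre[3] + radius * cos(ang)))
  })
  organ_contours(slices, "rectum")
}

# ---- dose ----------------------------------------------------------------

#' Generate one patient's 3D dose grid
#'
#' A spatially smooth field emulating a prostate plan: a plateau near the
#' patient's prescribed dose inside an ellipsoidal target placed
#' infero-posterior to a bladder (or anterior to a rectum), a sigmoidal
#' falloff with distance from the target surface, and a low dose bath.
#' Per-patient variation comes from the drawn prescription, small random
#' shifts of the target centre, and jitter of the target size and
#' falloff length. The grid covers the contour bounding box with margin;
#' voxel spacing defaults to (3, 2.5, 2.5) mm.
#'
#' @param spec A [cohort_spec()].
#' @param contours The patient's [organ_contours()].
#' @param patient_index Patient number; defaults to the attribute stored
#'   on `contours`.
#' @param spacing Voxel spacing (dz, dy, dx) in mm.
#' @param falloff Falloff length w in mm of the sigmoid
#'   `D = Rx * (bath + (1 - bath) * plogis(-s / w))` where s is the
#'   approximate signed distance to the target surface. `falloff = 0` is
#'   the limit case: prescription inside the target, bath outside.
#' @param bath Relative low-dose bath level (default 0.25).
#' @param noise_amp Relative amplitude of a smooth random modulation field
#'   (a few long-wavelength cosines, wavelengths 40-100 mm) multiplying
#'   the dose, emulating plan-to-plan variation that is not shared across
#'   the whole field. 0 gives the idealized noise-free field; default
#'   0.06.
#' @return List of class `patient_dose`: `grid` ([dose_grid()]),
#'   `prescription` (Gy), `n_fractions`, `target` (centre and semi-axes).
#' @export
generate_dose <- function(spec, contours,
                          patient_index = attr(contours, "patient_index"),
                          spacing = c(3, 2.5, 2.5), falloff = 6,
                          bath = 0.25, noise_amp = 0.06) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(contours, "organ_contours"))
  if (is.null(patient_index)) stop("`patient_index` required")
  set.seed(patient_seed(spec$seed, patient_index, 1L))
  rx <- max(40, stats::rnorm(1, spec$prescription_dose, spec$prescription_sd))
  nfx <- max(15L, round(stats::rnorm(1, spec$n_fractions, spec$fractions_sd)))
  # organ bounding box
  z <- contour_z(contours)
  yy <- range(unlist(lapply(contours$slices, function(s) s$vertices[, 1])))
  xx <- range(unlist(lapply(contours$slices, function(s) s$vertices[, 2])))
  jit <- stats::rnorm(3, 0, 4)
  semi <- c(25, 28, 30) * exp(stats::rnorm(3, 0, 0.08))   # (z, y, x) mm
  # the target ellipsoid is anchored to an organ wall point so the
  # adjacent wall receives near-prescription dose whatever the organ size:
  # postero-inferior bladder wall (prostate sits below and behind the
  # bladder) or anterior rectal wall (prostate sits in front of the rectum)
  if (contours$organ == "bladder") {
    zs <- vapply(contours$slices, function(s) s$z, numeric(1))
    ks <- which.min(abs(zs - (min(z) + 0.18 * diff(range(z)))))
    vtx <- contours$slices[[ks]]$vertices
    anchor <- c(zs[ks], max(vtx[, 1]), polygon_centroid(vtx)[2])
    dirn <- c(-0.8, 0.35, 0); dirn <- dirn / sqrt(sum(dirn^2))
  } else {
    zs <- vapply(contours$slices, function(s) s$z, numeric(1))
    ks <- which.min(abs(zs - mean(range(z))))
    vtx <- contours$slices[[ks]]$vertices
    anchor <- c(zs[ks], min(vtx[, 1]), polygon_centroid(vtx)[2])
    dirn <- c(0, -1, 0)
  }
  # distance from centre to ellipsoid surface along dirn, then pull the
  # centre back so the anchor sits `overlap` mm inside the target
  overlap <- 15
  d_surf <- 1 / sqrt(sum((dirn / semi)^2))
  ctr <- anchor + dirn * (d_surf - overlap) + jit
  cz <- ctr[1]; cy <- ctr[2]; cx <- ctr[3]
  w <- max(0, falloff * exp(stats::rnorm(1, 0, 0.15)))
  margin <- 30
  zg <- seq(min(z) - margin, max(z) + margin, by = spacing[1])
  yg <- seq(yy[1] - margin, yy[2] + margin, by = spacing[2])
  xg <- seq(xx[1] - margin, xx[2] + margin, by = spacing[3])
  # approximate signed distance to the target ellipsoid surface
  rho2 <- outer(outer(((zg - cz) / semi[1])^2, ((yg - cy) / semi[2])^2, `+`),
                ((xg - cx) / semi[3])^2, `+`)
  reff <- exp(mean(log(semi)))
  s <- (sqrt(rho2) - 1) * reff
  vals <- if (w == 0) {
    rx * (bath + (1 - bath) * (s <= 0))
  } else {
    rx * (bath + (1 - bath) * stats::plogis(-s / w))
  }
  if (noise_amp > 0) {
    # smooth modulation: 3 random plane-wave cosines, wavelengths 40-100 mm
    mod <- 0
    for (h in 1:3) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      kv <- 2 * pi / stats::runif(1, 40, 100) * u
      ph <- stats::runif(1, 0, 2 * pi)
      mod <- mod + cos(outer(outer(kv[1] * zg, kv[2] * yg, `+`),
                             kv[3] * xg, `+`) + ph)
    }
    vals <- vals * (1 + noise_amp / sqrt(3) * mod)
    vals[vals < 0] <- 0
  }
  grid <- dose_grid(vals, spacing = spacing,
                    origin = c(zg[1], yg[1], xg[1]))
  structure(list(grid = grid, prescription = rx, n_fractions = nfx,
                 target = list(centre = c(cz, cy, cx), semi_axes = semi,
                               falloff = w, bath = bath)),
            class = "patient_dose")
}

# ---- toxicity ------------------------------------------------------------

#' Generate one patient's toxicity records
#'
#' Baseline grade is Bernoulli(`baseline_prevalence`), mapped to grade 1.
#' The follow-up event probability follows a logistic link on the
#' planted region's dose excess (mean planted-region dose minus the
#' patient's whole-map mean dose):
#' `plogis(intercept + effect_size * (excess - dose_ref)
#' + baseline_boost * baseline_grade)`. Given an event, the maximum
#' follow-up grade is drawn from `grade_noise` (a latent severity
#' thresholded to grades 1-3) and placed at 12 or 24 months with the
#' other time point at most as severe; without an event both follow-up
#' grades are 0, so the maximum follow-up grade is >= 1 exactly when the
#' event was drawn.
#'
#' @param spec A [cohort_spec()].
#' @param map The patient's normalized [dsm()] (EQD2 recommended; 91 x 90).
#' @param patient_index Patient number; defaults to the attribute stored
#'   on `map` (set by [generate_cohort()]).
#' @return List: `records` (data frame, one row per endpoint with grade
#'   columns) and `truth_event_probability` (named per endpoint).
#' @export
generate_toxicity <- function(spec, map,
                              patient_index = attr(map, "patient_index")) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (inherits(map, "dsm")) {
    if (!all(dim(map$doses) == c(DSM_ROWS, DSM_COLS)))
      stop("map must be on the 91 x 90 grid")
    doses <- map$doses
  } else if (is.matrix(map) && all(dim(map) == c(DSM_ROWS, DSM_COLS))) {
    doses <- map
  } else stop("`map` must be a dsm or 91 x 90 matrix")
  if (is.null(patient_index)) stop("`patient_index` required")
  set.seed(patient_seed(spec$seed, patient_index, 2L))
  mean_planted <- mean(doses[spec$planted_region], na.rm = TRUE)
  # Drive the outcome by the planted region's dose EXCESS over the
  # patient's whole-map mean. Using the raw regional mean instead would
  # let the shared prescription scale correlate every voxel with the
  # outcome, washing out spatial specificity.
  excess <- mean_planted - mean(doses, na.rm = TRUE)
  recs <- vector("list", length(spec$endpoints))
  truth <- numeric(length(spec$endpoints))
  for (i in seq_along(spec$endpoints)) {
    baseline <- as.integer(stats::runif(1) < spec$baseline_prevalence)
    p_event <- stats::plogis(spec$intercept +
                               spec$effect_size * (excess - spec$dose_ref) +
                               spec$baseline_boost * baseline)
    event <- stats::runif(1) < p_event
    if (event) {
      gmax <- sample.int(3L, 1L, prob = spec$grade_noise)
      at24 <- stats::runif(1) < 0.5
      other <- sample.int(gmax + 1L, 1L) - 1L       # 0..gmax
      g12 <- if (at24) other else gmax
      g24 <- if (at24) gmax else other
    } else {
      g12 <- 0L; g24 <- 0L
    }
    recs[[i]] <- data.frame(patient_id = patient_index,
                            endpoint = spec$endpoints[i],
                            grade_baseline = baseline,
                            grade_12m = g12, grade_24m = g24,
                            stringsAsFactors = FALSE)
    truth[i] <- p_event
  }
  names(truth) <- spec$endpoints
  list(records = do.call(rbind, recs), truth_event_probability = truth,
       mean_planted_dose = mean_planted)
}

# ---- whole cohort --------------------------------------------------------

#' Generate a complete synthetic cohort
#'
#' Runs geometry, dose, unwrapping, normalization, EQD2 conversion and
#' toxicity generation for every patient, returning the analysable cohort
#' bundle: a patient-by-voxel EQD2 stack, the toxicity grade table, and
#' per-patient metadata. Raw dose grids and contours are dropped by
#' default to keep the bundle small.
#'
#' @param spec A [cohort_spec()].
#' @param alpha_beta Alpha/beta (Gy) for the EQD2 conversion (default 1).
#' @param keep_raw Keep each patient's contours and dose grid (memory-
#'   heavy; default FALSE).
#' @return Object of class `drm_cohort`: `stack` ([dsm_stack()] of EQD2
#'   maps), `grades` (toxicity table), `meta` (per-patient prescription,
#'   fractions, truth event probability, mean planted dose), `spec`,
#'   and optionally `patients` (raw per-patient data).
#' @export
generate_cohort <- function(spec, alpha_beta = 1, keep_raw = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  dsms <- vector("list", spec$n_patients)
  grades <- vector("list", spec$n_patients)
  meta <- vector("list", spec$n_patients)
  patients <- if (keep_raw) vector("list", spec$n_patients) else NULL
  for (i in seq_len(spec$n_patients)) {
    cont <- generate_organ_geometry(spec, i)
    pd <- generate_dose(spec, cont, patient_index = i)
    raw <- if (spec$organ == "bladder") {
      unwrap_bladder_spherical(cont, pd$grid)
    } else {
      unwrap_rectum_cylindrical(cont, pd$grid)
    }
    map <- if (inherits(raw, "dsm")) raw else normalize_dsm(raw)
    map <- eqd2_dsm(map, pd$n_fractions, alpha_beta)
    attr(map, "patient_index") <- i
    tox <- generate_toxicity(spec, map, patient_index = i)
    dsms[[i]] <- map
    grades[[i]] <- tox$records
    meta[[i]] <- data.frame(patient_id = i, prescription = pd$prescription,
                            n_fractions = pd$n_fractions,
                            mean_planted_dose = tox$mean_planted_dose,
                            truth_event_probability =
                              tox$truth_event_probability[1])
    if (keep_raw)
      patients[[i]] <- list(contours = cont, dose = pd, dsm = map,
                            toxicity = tox)
  }
  structure(list(stack = dsm_stack(dsms), grades = do.call(rbind, grades),
                 meta = do.call(rbind, meta), spec = spec,
                 patients = patients),
            class = "drm_cohort")
}

#' @export
print.drm_cohort <- function(x, ...) {
  cat(sprintf("<drm_cohort> %d patients, %s, %d endpoints, %d/%d commonly valid voxels\n",
              x$spec$n_patients, x$spec$organ, length(x$spec$endpoints),
              sum(x$stack$valid), length(x$stack$valid)))
  invisible(x)
}

#' Fast exchangeable-null cohort on a reduced map
#'
#' Generates smooth correlated random dose maps (a Gaussian random field
#' from kernel-smoothed white noise, plus a fixed mean-dose gradient and
#' a patient-level offset) together with outcome labels drawn
#' independently of dose. Because labels carry no dose information, any
#' voxel declared significant is a family-wise false positive — this is
#' the construction used to check the calibration of the permutation
#' Tmax threshold, on a reduced grid so hundreds of replicate cohorts are
#' cheap.
#'
#' @param n_patients Cohort size (default 60).
#' @param rows,cols Map size (default 20 x 20).
#' @param event_rate Marginal probability of an event label (default 0.3).
#'   Labels are redrawn until both groups have >= 2 members, which
#'   preserves exchangeability.
#' @param smooth_sd Gaussian kernel SD of the spatial smoothing, in
#'   voxels (default 2).
#' @param seed Integer seed.
#' @return List: `X` (patients x voxels matrix), `labels` (0/1),
#'   `dim` = c(rows, cols).
#' @export
simulate_null_cohort <- function(n_patients = 60L, rows = 20L, cols = 20L,
                                 event_rate = 0.3, smooth_sd = 2, seed = 1L) {
  set.seed(as.integer(seed))
  half <- ceiling(3 * smooth_sd)
  k <- stats::dnorm(seq(-half, half), sd = smooth_sd)
  k <- k / sum(k)
  pr <- rows + 2 * half; pc <- cols + 2 * half
  base <- outer(seq_len(rows), seq_len(cols),
                function(i, j) 40 + 25 * exp(-((i - rows / 2)^2 +
                                                 (j - cols / 2)^2) /
                                               (2 * (rows / 3)^2)))
  X <- matrix(0, n_patients, rows * cols)
  for (p in seq_len(n_patients)) {
    z <- matrix(stats::rnorm(pr * pc), pr, pc)
    z <- apply(z, 2, function(col) stats::filter(col, k, sides = 2))
    z <- t(apply(z, 1, function(row) stats::filter(row, k, sides = 2)))
    z <- z[half + seq_len(rows), half + seq_len(cols)]
    z <- z / stats::sd(as.vector(z))
    X[p, ] <- as.vector(base + 6 * z + stats::rnorm(1, 0, 3))
  }
  repeat {
    labels <- stats::rbinom(n_patients, 1L, event_rate)
    if (sum(labels) >= 2L && sum(1 - labels) >= 2L) break
  }
  list(X = X, labels = labels, dim = c(rows, cols))
}
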