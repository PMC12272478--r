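# Core data containers: dose grids, organ contours, dose-surface maps.

DSM_ROWS <- 91L
DSM_COLS <- 90L

#' Construct a 3D dose grid
#'
#' A scalar dose field on a regular lattice. Values are indexed
#' `[z, y, x]`; `spacing` and `origin` are given in the same (z, y, x)
#' order, in millimetres. `origin` is the physical coordinate of the
#' centre of voxel `[1, 1, 1]`.
#'
#' @param values 3D numeric array of dose in Gy, dimension (nz, ny, nx).
#' @param spacing Numeric length-3, voxel spacing (dz, dy, dx) in mm; all > 0.
#' @param origin Numeric length-3, coordinate (z, y, x) in mm of the first
#'   voxel centre.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array indexed [z, y, x]")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (dz, dy, dx) in mm")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (z, y, x) in mm")
  if (any(!is.finite(values)) || any(values < 0))
    stop("dose values must be finite and non-negative")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_grid> %d x %d x %d voxels (z,y,x), spacing %s mm, dose %.1f-%.1f Gy\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = "/"),
              min(x$values), max(x$values)))
  invisible(x)
}

# physical voxel-centre coordinates along one axis (1 = z, 2 = y, 3 = x)
grid_axis <- function(grid, k) {
  grid$origin[k] + (seq_len(dim(grid$values)[k]) - 1) * grid$spacing[k]
}

#' Construct an organ contour set
#'
#' Ordered closed planar polygons, one per axial slice, describing the
#' outer wall of one organ. Polygons are stored as open rings (the closing
#' edge from the last back to the first vertex is implicit) with vertices
#' in (y, x) mm.
#'
#' @param slices List of slices; each a list with `z` (slice position, mm)
#'   and `vertices` (numeric matrix with columns y, x in mm, at least 3
#'   rows, no repeated closing vertex).
#' @param organ `"bladder"` or `"rectum"`.
#' @return An object of class `organ_contours`, slices sorted by z
#'   (inferior to superior).
#' @export
organ_contours <- function(slices, organ = c("bladder", "rectum")) {
  organ <- match.arg(organ)
  if (!is.list(slices) || length(slices) < 2L)
    stop("need at least 2 contour slices")
  for (s in slices) {
    if (is.null(s$z) || !is.finite(s$z)) stop("every slice needs a finite z")
    v <- s$vertices
    if (!is.matrix(v) || ncol(v) != 2L || nrow(v) < 3L || any(!is.finite(v)))
      stop("every slice needs a (y, x) vertex matrix with >= 3 finite rows")
  }
  z <- vapply(slices, function(s) s$z, numeric(1))
  if (anyDuplicated(z)) stop("duplicate slice z positions")
  slices <- slices[order(z)]
  structure(list(slices = slices, organ = organ), class = "organ_contours")
}

#' @export
print.organ_contours <- function(x, ...) {
  z <- contour_z(x)
  cat(sprintf("<organ_contours> %s, %d slices, z %.1f to %.1f mm\n",
              x$organ, length(x$slices), min(z), max(z)))
  invisible(x)
}

contour_z <- function(contours)
  vapply(contours$slices, function(s) s$z, numeric(1))

# signed shoelace area of an open (y, x) ring; positive when the ring is
# counter-clockwise in the (x, y) plane
polygon_area <- function(v) {
  y <- v[, 1]; x <- v[, 2]
  y2 <- c(y[-1], y[1]); x2 <- c(x[-1], x[1])
  sum(x * y2 - x2 * y) / 2
}

# area centroid (y, x) of a simple polygon ring
polygon_centroid <- function(v) {
  y <- v[, 1]; x <- v[, 2]
  y2 <- c(y[-1], y[1]); x2 <- c(x[-1], x[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(y), mean(x)))
  c(sum((y + y2) * cr), sum((x + x2) * cr)) / (6 * a)
}

#' Enclosed volume of a contour set
#'
#' Trapezoidal integration of absolute slice polygon areas along z. Used
#' for reporting and for checking generated geometry against the target
#' organ-volume distribution.
#'
#' @param contours An [organ_contours()] object.
#' @return Volume in cm^3.
#' @export
contour_volume <- function(contours) {
  stopifnot(inherits(contours, "organ_contours"))
  z <- contour_z(contours)
  a <- vapply(contours$slices, function(s) abs(polygon_area(s$vertices)),
              numeric(1))
  # trapezoid between slices plus half-spacing end caps treated as cones
  v <- sum(diff(z) * (a[-1] + a[-length(a)]) / 2)
  v / 1000  # mm^3 -> cm^3
}

#' Construct a dose-surface map
#'
#' The normalized 2D representation of dose on an organ surface: a 91 x 90
#' matrix of dose values with a validity mask. Invalid voxels hold `NA` in
#' `doses` and are excluded from all downstream statistics; they are never
#' silently zero.
#'
#' @param doses 91 x 90 numeric matrix (Gy), `NA` allowed on invalid voxels.
#' @param valid 91 x 90 logical matrix; `doses` must be finite where `TRUE`.
#' @param organ `"bladder"` or `"rectum"`.
#' @param dose_kind `"physical"` or `"EQD2"`.
#' @return An object of class `dsm`.
#' @seealso [dsm_axes()] for the anatomical row/column conventions.
#' @export
dsm <- function(doses, valid = is.finite(doses),
                organ = c("bladder", "rectum"),
                dose_kind = c("physical", "EQD2")) {
  organ <- match.arg(organ); dose_kind <- match.arg(dose_kind)
  if (!is.matrix(doses) || !all(dim(doses) == c(DSM_ROWS, DSM_COLS)))
    stop(sprintf("`doses` must be a %d x %d matrix", DSM_ROWS, DSM_COLS))
  if (!is.logical(valid) || !all(dim(valid) == dim(doses)))
    stop("`valid` must be a logical matrix matching `doses`")
  if (any(!is.finite(doses[valid])))
    stop("doses must be finite on valid voxels")
  doses[!valid] <- NA_real_
  structure(list(doses = doses, valid = valid, organ = organ,
                 dose_kind = dose_kind, axes = dsm_axes(organ)),
            class = "dsm")
}

#' @export
print.dsm <- function(x, ...) {
  cat(sprintf("<dsm> %s (%s), %d/%d valid voxels, dose %.1f-%.1f Gy\n",
              x$organ, x$dose_kind, sum(x$valid), length(x$valid),
              min(x$doses, na.rm = TRUE), max(x$doses, na.rm = TRUE)))
  invisible(x)
}

#' Anatomical axis conventions for dose-surface maps
#'
#' A single documented constant table naming what the rows and columns of
#' a 91 x 90 map mean, used by the unwrapping functions and by plot
#' annotation. Bladder maps come from spherical unwrapping: rows follow
#' the polar angle theta from the superior pole (row 1) to the inferior
#' pole (row 91); columns follow the azimuth phi on a half-open
#' `[0, 360)` degree circle starting at anterior (column 1) and
#' increasing towards the patient's left, so patient-left is near column
#' 23, posterior near column 46 and patient-right near column 68.
#' Rectum maps come from cylindrical unwrapping with a posterior incision:
#' rows are axial slices from inferior (row 1) to superior (row 91);
#' columns sweep from just left of posterior, through the patient's
#' right, anterior at the map centre (column 45/46 boundary), through the
#' patient's left and back to posterior.
#'
#' @param organ `"bladder"` or `"rectum"`.
#' @return List with elements `rows`, `cols`, and `landmarks` (named
#'   vector of approximate column indices of anatomical directions).
#' @export
dsm_axes <- function(organ = c("bladder", "rectum")) {
  organ <- match.arg(organ)
  if (organ == "bladder") {
    list(rows = "polar angle theta: superior pole (row 1) to inferior pole (row 91)",
         cols = "azimuth phi in [0, 360): anterior (col 1), increasing to patient left",
         landmarks = c(anterior = 1, left = 23, posterior = 46, right = 68))
  } else {
    list(rows = "axial slices: inferior (row 1) to superior (row 91)",
         cols = "azimuth about slice centroid, cut at posterior; anterior at map centre",
         landmarks = c(posterior_left_edge = 1, right = 23, anterior = 45.5,
                       left = 68, posterior_right_edge = 90))
  }
}

#' Stack dose-surface maps into a patients-by-voxels matrix
#'
#' Flattens a list of [dsm()] objects into the matrix representation used
#' by the voxel-wise statistics: one row per patient, one column per map
#' voxel (column-major over the 91 x 90 grid). The common validity mask is
#' the conjunction of the individual masks, so a voxel enters the analysis
#' only when it is analysable for every patient.
#'
#' @param dsms List of [dsm()] objects with identical organ and dose kind.
#' @return List of class `dsm_stack` with `X` (n x 8190 matrix), `valid`
#'   (length-8190 logical), `dim` (c(91, 90)), `organ`, `dose_kind`.
#' @export
dsm_stack <- function(dsms) {
  if (inherits(dsms, "dsm_stack")) return(dsms)
  stopifnot(is.list(dsms), length(dsms) >= 1L,
            all(vapply(dsms, inherits, logical(1), "dsm")))
  organ <- unique(vapply(dsms, function(d) d$organ, character(1)))
  kind <- unique(vapply(dsms, function(d) d$dose_kind, character(1)))
  if (length(organ) != 1L || length(kind) != 1L)
    stop("all maps must share one organ and one dose kind")
  X <- t(vapply(dsms, function(d) as.vector(d$doses),
                numeric(DSM_ROWS * DSM_COLS)))
  valid <- Reduce(`&`, lapply(dsms, function(d) as.vector(d$valid)))
  structure(list(X = X, valid = valid, dim = c(DSM_ROWS, DSM_COLS),
                 organ = organ, dose_kind = kind),
            class = "dsm_stack")
}

# accept dsm_stack, plain matrix, or list of dsm; returns list(X, valid, dim)
as_stack <- function(x) {
  if (inherits(x, "dsm_stack")) return(x)
  if (is.matrix(x)) {
    return(structure(list(X = x, valid = rep(TRUE, ncol(x)),
                          dim = c(1L, ncol(x)), organ = NA, dose_kind = NA),
                     class = "dsm_stack"))
  }
  dsm_stack(x)
}
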