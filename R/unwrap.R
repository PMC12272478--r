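# Surface unwrapping: contours + 3D dose -> normalized dose-surface maps.
#
# Spherical unwrapping (bladder): rays from the organ's centre of mass at
# theta = 0..180 deg in 2 deg steps (91 rows) and phi in [0, 360) deg in
# 4 deg steps (90 columns, no duplicated seam). Cylindrical unwrapping
# (rectum): per-slice rays from the slice centroid, map cut at posterior
# so anterior sits at the central column; rows (slices) are resampled to
# 91 by normalize_dsm().

#' Trilinear interpolation of a dose grid
#'
#' @param grid A [dose_grid()].
#' @param pts Numeric matrix, one row per query point, columns (z, y, x)
#'   in mm.
#' @return Numeric vector of interpolated dose; `NA` where a point falls
#'   outside the grid (interpolation never extrapolates).
#' @export
interp_trilinear <- function(grid, pts) {
  stopifnot(inherits(grid, "dose_grid"), is.matrix(pts), ncol(pts) == 3L)
  d <- dim(grid$values)
  # fractional voxel indices
  f1 <- (pts[, 1] - grid$origin[1]) / grid$spacing[1] + 1
  f2 <- (pts[, 2] - grid$origin[2]) / grid$spacing[2] + 1
  f3 <- (pts[, 3] - grid$origin[3]) / grid$spacing[3] + 1
  ok <- f1 >= 1 & f1 <= d[1] & f2 >= 1 & f2 <= d[2] & f3 >= 1 & f3 <= d[3] &
    is.finite(f1) & is.finite(f2) & is.finite(f3)
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  f1 <- f1[ok]; f2 <- f2[ok]; f3 <- f3[ok]
  i1 <- pmin(floor(f1), d[1] - 1L); w1 <- f1 - i1
  i2 <- pmin(floor(f2), d[2] - 1L); w2 <- f2 - i2
  i3 <- pmin(floor(f3), d[3] - 1L); w3 <- f3 - i3
  v <- grid$values
  idx <- function(a, b, cc) v[a + (b - 1) * d[1] + (cc - 1) * (d[1] * d[2])]
  out[ok] <-
    (1 - w1) * ((1 - w2) * ((1 - w3) * idx(i1,     i2,     i3) +
                              w3      * idx(i1,     i2,     i3 + 1)) +
                  w2      * ((1 - w3) * idx(i1,     i2 + 1, i3) +
                              w3      * idx(i1,     i2 + 1, i3 + 1))) +
    w1       * ((1 - w2) * ((1 - w3) * idx(i1 + 1, i2,     i3) +
                              w3      * idx(i1 + 1, i2,     i3 + 1)) +
                  w2      * ((1 - w3) * idx(i1 + 1, i2 + 1, i3) +
                              w3      * idx(i1 + 1, i2 + 1, i3 + 1)))
  out
}

# ---- surface model -------------------------------------------------------
#
# The in-organ predicate is built from the slice polygons: each slice is
# reduced to its centroid and a radial profile r(alpha) sampled on a fine
# angular lattice (alpha measured like phi: 0 = anterior, increasing to
# patient left). Between slices both centroid and profile are linearly
# interpolated. This assumes slices are star-shaped about their centroid,
# which is the stated precondition of spherical unwrapping.

SURF_N_ANG <- 720L

surface_model <- function(contours) {
  z <- contour_z(contours)
  K <- length(z)
  ang_grid <- seq(0, 2 * pi, length.out = SURF_N_ANG + 1L)[-(SURF_N_ANG + 1L)]
  cent <- matrix(0, K, 2)   # (y, x)
  prof <- matrix(0, K, SURF_N_ANG)
  area <- numeric(K)
  for (k in seq_len(K)) {
    v <- contours$slices[[k]]$vertices
    cen <- polygon_centroid(v)
    dy <- v[, 1] - cen[1]; dx <- v[, 2] - cen[2]
    a <- atan2(dx, -dy) %% (2 * pi)   # 0 = anterior (-y), increasing to left (+x)
    r <- sqrt(dy^2 + dx^2)
    o <- order(a)
    a <- a[o]; r <- r[o]
    # periodic linear interpolation of vertex radii onto the angular lattice
    aa <- c(a[length(a)] - 2 * pi, a, a[1] + 2 * pi)
    rr <- c(r[length(r)], r, r[1])
    prof[k, ] <- stats::approx(aa, rr, xout = ang_grid, rule = 2)$y
    cent[k, ] <- cen
    area[k] <- abs(polygon_area(v))
  }
  list(z = z, cent = cent, prof = prof, area = area,
       ang_step = 2 * pi / SURF_N_ANG)
}

# vectorized point-in-organ predicate; pts columns (z, y, x)
in_organ <- function(model, pts) {
  n <- nrow(pts)
  inside <- rep(FALSE, n)
  z <- pts[, 1]
  K <- length(model$z)
  k <- findInterval(z, model$z)
  okz <- k >= 1L & k < K
  at_top <- z == model$z[K]
  k[at_top] <- K - 1L
  okz <- okz | at_top
  if (!any(okz)) return(inside)
  k <- k[okz]
  w <- (z[okz] - model$z[k]) / (model$z[k + 1L] - model$z[k])
  cy <- (1 - w) * model$cent[k, 1] + w * model$cent[k + 1L, 1]
  cx <- (1 - w) * model$cent[k, 2] + w * model$cent[k + 1L, 2]
  dy <- pts[okz, 2] - cy; dx <- pts[okz, 3] - cx
  a <- atan2(dx, -dy)            # (-pi, pi]
  a[a < 0] <- a[a < 0] + 2 * pi
  ai <- a / model$ang_step
  j <- floor(ai); wa <- ai - j   # j in 0..SURF_N_ANG (ai == 2pi edge case)
  j[j >= SURF_N_ANG] <- SURF_N_ANG - 1L
  jn <- j + 1                    # next angular node, wraps at the seam
  jn[jn >= SURF_N_ANG] <- 0
  # linear indices into the K x SURF_N_ANG profile matrix
  i11 <- k + j * K; i12 <- k + jn * K
  pk  <- (1 - wa) * model$prof[i11] + wa * model$prof[i12]
  pk1 <- (1 - wa) * model$prof[i11 + 1] + wa * model$prof[i12 + 1]
  rsurf <- (1 - w) * pk + w * pk1
  inside[okz] <- dy * dy + dx * dx <= rsurf * rsurf
  inside
}

# volume-weighted centre of mass (z, y, x) from the surface model
organ_com <- function(model) {
  wts <- model$area
  c(sum(model$z * wts), sum(model$cent[, 1] * wts),
    sum(model$cent[, 2] * wts)) / sum(wts)
}

#' Spherical unwrapping of a bladder-like organ surface
#'
#' Casts rays from the organ's centre of mass on a (theta, phi) lattice:
#' theta from 0 to 180 degrees inclusive (default 2 degree steps, 91
#' rows; theta = 0 is the superior pole) and phi on the half-open
#' `[0, 360)` circle (default 4 degree steps, 90 columns, no duplicated
#' seam). For each direction the surface radius is found by bisection of
#' a point-in-organ predicate built from the slice polygons (0.1 mm
#' tolerance) and the dose at the surface point is read from the grid by
#' trilinear interpolation.
#'
#' Rays that fail to produce a surface point inside the dose grid are
#' marked invalid (with a warning); a centre of mass outside the organ is
#' a whole-map failure and raises an error.
#'
#' @param contours [organ_contours()], star-shaped about the centre of mass.
#' @param dose [dose_grid()] covering the organ surface.
#' @param theta_step_deg,phi_step_deg Angular steps in degrees. The
#'   defaults (2, 4) give the standard 91 x 90 map.
#' @return A [dsm()] with `dose_kind = "physical"`.
#' @export
unwrap_bladder_spherical <- function(contours, dose,
                                     theta_step_deg = 2, phi_step_deg = 4) {
  stopifnot(inherits(contours, "organ_contours"), inherits(dose, "dose_grid"))
  model <- surface_model(contours)
  com <- organ_com(model)
  if (!in_organ(model, matrix(com, 1)))
    stop("organ centre of mass lies outside the contours; cannot unwrap")
  thetas <- seq(0, 180, by = theta_step_deg) * pi / 180
  phis <- seq(0, 360 - phi_step_deg, by = phi_step_deg) * pi / 180
  nr <- length(thetas); nc <- length(phis)
  th <- rep(thetas, times = nc); ph <- rep(phis, each = nr)
  # direction: z superior at theta = 0; phi = 0 anterior (-y), increasing to left (+x)
  uz <- cos(th); ux <- sin(th) * sin(ph); uy <- -sin(th) * cos(ph)
  # upper bound on surface radius: max vertex distance from the COM
  rmax <- 0
  for (s in contours$slices) {
    d2 <- (s$z - com[1])^2 + (s$vertices[, 1] - com[2])^2 +
      (s$vertices[, 2] - com[3])^2
    rmax <- max(rmax, sqrt(max(d2)))
  }
  hi <- rep(rmax * 1.05 + 1, nr * nc)
  lo <- rep(0, nr * nc)
  n_iter <- ceiling(log2((rmax * 1.05 + 1) / 0.1)) + 1L
  for (it in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    pts <- cbind(com[1] + mid * uz, com[2] + mid * uy, com[3] + mid * ux)
    ins <- in_organ(model, pts)
    lo[ins] <- mid[ins]
    hi[!ins] <- mid[!ins]
  }
  r <- (lo + hi) / 2
  surf <- cbind(com[1] + r * uz, com[2] + r * uy, com[3] + r * ux)
  dval <- interp_trilinear(dose, surf)
  bad_ray <- lo == 0            # never entered the organ along this ray
  dval[bad_ray] <- NA_real_
  n_bad <- sum(!is.finite(dval))
  if (n_bad > 0)
    warning(sprintf("%d of %d surface samples invalid (ray missed surface or left dose grid)",
                    n_bad, length(dval)))
  doses <- matrix(dval, nr, nc)
  if (nr == DSM_ROWS && nc == DSM_COLS) {
    dsm(doses, valid = is.finite(doses), organ = contours$organ,
        dose_kind = "physical")
  } else {
    raw_map(doses, is.finite(doses), organ = contours$organ)
  }
}

# intermediate (pre-normalization) map with arbitrary rows/cols
raw_map <- function(doses, valid, organ) {
  structure(list(doses = doses, valid = valid, organ = organ,
                 dose_kind = "physical"), class = "raw_map")
}

#' Cylindrical unwrapping of a rectum-like organ surface
#'
#' For each axial slice, casts `n_phi` rays in the slice plane from the
#' slice centroid and records the dose (trilinear) where each ray first
#' crosses the contour polygon. The angular origin implements the
#' posterior incision: the map is cut at posterior, columns sweep through
#' the patient's right, anterior at the central column, then the
#' patient's left. Rows are slices ordered inferior to superior; pass the
#' result to [normalize_dsm()] to obtain the standard 91 x 90 grid.
#'
#' Slices whose centroid falls outside their polygon (e.g. crescent
#' shapes) cannot be unwrapped directly; their rows are filled by linear
#' interpolation between the nearest valid slices where both neighbours
#' exist, and marked invalid otherwise.
#'
#' @param contours [organ_contours()] with at least 2 slices.
#' @param dose [dose_grid()] covering the slice polygons.
#' @param n_phi Number of angular samples per slice (default 90).
#' @return A `raw_map` (slices x `n_phi`) ready for [normalize_dsm()].
#' @export
unwrap_rectum_cylindrical <- function(contours, dose, n_phi = 90L) {
  stopifnot(inherits(contours, "organ_contours"), inherits(dose, "dose_grid"))
  z <- contour_z(contours)
  K <- length(z)
  # column angle delta measured from anterior, increasing towards patient
  # left; columns span (-180, 180] so the cut sits at posterior and
  # anterior falls at the map centre
  delta <- ((seq_len(n_phi) - 0.5) / n_phi * 360 - 180) * pi / 180
  dirx <- sin(delta); diry <- -cos(delta)
  doses <- matrix(NA_real_, K, n_phi)
  slice_ok <- logical(K)
  for (k in seq_len(K)) {
    v <- contours$slices[[k]]$vertices
    cen <- polygon_centroid(v)
    ring <- rbind(v, v[1, , drop = FALSE])
    if (!mgcv::in.out(ring[, c(2, 1)], matrix(cen[c(2, 1)], 1))) next
    slice_ok[k] <- TRUE
    r <- ray_polygon_radius(cen, v, dirx, diry)
    pts <- cbind(z[k], cen[1] + r * diry, cen[2] + r * dirx)
    doses[k, ] <- interp_trilinear(dose, pts)
  }
  if (!any(slice_ok))
    stop("no slice centroid lies inside its contour; cannot unwrap")
  valid <- is.finite(doses)
  # adjacent-slice interpolation for centroid-outside slices
  good <- which(slice_ok)
  for (k in which(!slice_ok)) {
    below <- good[good < k]; above <- good[good > k]
    if (length(below) && length(above)) {
      k0 <- max(below); k1 <- min(above)
      w <- (z[k] - z[k0]) / (z[k1] - z[k0])
      doses[k, ] <- (1 - w) * doses[k0, ] + w * doses[k1, ]
      valid[k, ] <- valid[k0, ] & valid[k1, ]
    } else {
      valid[k, ] <- FALSE
    }
  }
  doses[!valid] <- NA_real_
  raw_map(doses, valid, organ = contours$organ)
}

# first crossing of rays (from point `cen`, directions dirx/diry) with the
# edges of polygon `v`; returns one radius per ray
ray_polygon_radius <- function(cen, v, dirx, diry) {
  e1y <- v[, 1]; e1x <- v[, 2]
  e2y <- c(v[-1, 1], v[1, 1]); e2x <- c(v[-1, 2], v[1, 2])
  ey <- e2y - e1y; ex <- e2x - e1x
  n_ray <- length(dirx); n_edge <- nrow(v)
  r <- rep(NA_real_, n_ray)
  for (i in seq_len(n_ray)) {
    dx <- dirx[i]; dy <- diry[i]
    den <- dx * ey - dy * ex
    py <- e1y - cen[1]; px <- e1x - cen[2]
    t <- (px * ey - py * ex) / den
    s <- (py * dx - px * dy) / -den
    # s tolerance: a ray through a vertex must register on at least one
    # of the two edges meeting there despite rounding
    hit <- is.finite(t) & is.finite(s) & t > 1e-9 & s >= -1e-9 & s <= 1 + 1e-9
    if (any(hit)) r[i] <- min(t[hit])
  }
  r
}

#' Spatially normalize a dose-surface map to the standard grid
#'
#' Bilinear resampling of a 2D surface-dose map onto the common
#' `target_rows` x `target_cols` lattice so maps are comparable across
#' patients with different organ sizes. The validity mask is resampled
#' conservatively: an output voxel is valid only if every input voxel
#' contributing to it is valid.
#'
#' @param raw A `raw_map` from an unwrapping function, a [dsm()], or a
#'   plain numeric matrix (then assumed fully valid).
#' @param target_rows,target_cols Output lattice size (default 91 x 90).
#' @param organ,dose_kind Used only when `raw` is a plain matrix.
#' @return A [dsm()] when the target is 91 x 90, else a `raw_map`.
#' @export
normalize_dsm <- function(raw, target_rows = 91L, target_cols = 90L,
                          organ = c("bladder", "rectum"),
                          dose_kind = c("physical", "EQD2")) {
  if (is.matrix(raw)) {
    raw <- list(doses = raw, valid = is.finite(raw),
                organ = match.arg(organ), dose_kind = match.arg(dose_kind))
  }
  M <- raw$doses; V <- raw$valid
  if (nrow(M) < 2L || ncol(M) < 2L)
    stop("map must be at least 2 x 2 to resample")
  kind <- if (!is.null(raw$dose_kind)) raw$dose_kind else "physical"
  src_r <- 1 + (seq_len(target_rows) - 1) * (nrow(M) - 1) / (target_rows - 1)
  src_c <- 1 + (seq_len(target_cols) - 1) * (ncol(M) - 1) / (target_cols - 1)
  i <- pmin(floor(src_r), nrow(M) - 1L); wr <- src_r - i
  j <- pmin(floor(src_c), ncol(M) - 1L); wc <- src_c - j
  Mz <- M; Mz[!V] <- 0
  blend <- function(A) {
    A11 <- A[i, j, drop = FALSE]; A21 <- A[i + 1L, j, drop = FALSE]
    A12 <- A[i, j + 1L, drop = FALSE]; A22 <- A[i + 1L, j + 1L, drop = FALSE]
    WR <- matrix(wr, target_rows, target_cols)
    WC <- matrix(wc, target_rows, target_cols, byrow = TRUE)
    (1 - WR) * ((1 - WC) * A11 + WC * A12) + WR * ((1 - WC) * A21 + WC * A22)
  }
  out <- blend(Mz)
  vnum <- blend(matrix(as.numeric(V), nrow(M), ncol(M)))
  vout <- vnum > 1 - 1e-9          # all contributing inputs valid
  out[!vout] <- NA_real_
  if (target_rows == DSM_ROWS && target_cols == DSM_COLS) {
    dsm(out, valid = vout, organ = raw$organ, dose_kind = kind)
  } else {
    structure(list(doses = out, valid = vout, organ = raw$organ,
                   dose_kind = kind), class = "raw_map")
  }
}

#' Mark map voxels as excluded
#'
#' Applies a manual exclusion mask (e.g. for unwrapping artifacts near
#' the bladder trigone, which are identified visually rather than
#' automatically): masked voxels become invalid; dose values elsewhere
#' are untouched.
#'
#' @param x A [dsm()].
#' @param mask 91 x 90 logical matrix; `TRUE` marks voxels to exclude.
#' @return The map with the reduced validity mask.
#' @export
apply_exclusion_mask <- function(x, mask) {
  stopifnot(inherits(x, "dsm"))
  if (!is.logical(mask) || !all(dim(mask) == dim(x$valid)))
    stop("`mask` must be a logical matrix matching the map")
  x$valid <- x$valid & !mask
  x$doses[!x$valid] <- NA_real_
  x
}
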