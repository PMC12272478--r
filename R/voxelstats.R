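# Voxel-wise two-group inference on dose-surface maps: Welch t-maps,
# Shapiro-Wilk normality screening, standardized Mann-Whitney maps,
# permutation Tmax family-wise error control, and Dice overlap.

# ---- helpers -------------------------------------------------------------

# Welch t for all permutations at once. X: n x V dose matrix; P: B x n 0/1
# membership matrix for group 1 (each row sums to n1). Returns B x V matrix
# of t values (NaN where a denominator vanishes).
welch_perm_stats <- function(X, P, n1) {
  n <- nrow(X); n2 <- n - n1
  X2 <- X * X
  tot <- colSums(X); tot2 <- colSums(X2)
  S1 <- P %*% X; Q1 <- P %*% X2
  m1 <- S1 / n1
  v1 <- (Q1 - S1 * m1) / (n1 - 1)
  S2 <- sweep(-S1, 2, tot, `+`)
  Q2 <- sweep(-Q1, 2, tot2, `+`)
  m2 <- S2 / n2
  v2 <- (Q2 - S2 * m2) / (n2 - 1)
  v1[v1 < 0] <- 0; v2[v2 < 0] <- 0
  den <- sqrt(v1 / n1 + v2 / n2)
  out <- (m1 - m2) / den
  out[den == 0] <- NaN
  out
}

# standardized Mann-Whitney U (tie-corrected normal approximation) for all
# permutations; R1 = group-1 rank sums come from one matrix product over
# the fixed per-voxel ranks. Returns list(z = B x V, U = B x V raw U).
mw_perm_stats <- function(X, P, n1) {
  n <- nrow(X); n2 <- n - n1
  R <- apply(X, 2, rank)            # mid-ranks, n x V
  ties_term <- apply(X, 2, function(col) {
    tt <- table(col); sum(tt^3 - tt)
  })
  R1 <- P %*% R
  U <- R1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sig2 <- n1 * n2 / 12 * ((n + 1) - ties_term / (n * (n - 1)))
  sig <- sqrt(pmax(sig2, 0))
  z <- sweep(U, 2, mu, `-`)
  z <- sweep(z, 2, sig, `/`)
  z[, sig == 0] <- NaN
  list(z = z, U = U)
}

row_max <- function(M) apply(M, 1, function(r) {
  r <- r[is.finite(r)]
  if (length(r)) max(r) else NA_real_
})
row_min <- function(M) apply(M, 1, function(r) {
  r <- r[is.finite(r)]
  if (length(r)) min(r) else NA_real_
})

restore_dim <- function(v, dm) {
  m <- matrix(v, dm[1], dm[2]); m
}

# ---- observed maps -------------------------------------------------------

#' Voxel-wise Welch t-map between event and non-event groups
#'
#' At each analysable voxel computes
#' \deqn{t = (\bar X_1 - \bar X_2) / \sqrt{S_1^2/N_1 + S_2^2/N_2}}
#' with group 1 the event group, so positive t means events received the
#' higher dose. Sample variances use the n-1 denominator. Voxels whose
#' pooled denominator is zero (dose constant within both groups) are
#' removed from the valid mask rather than epsilon-padded.
#'
#' @param event,nonevent Patient-by-voxel matrices (or [dsm_stack()] /
#'   lists of [dsm()]), each with at least 2 rows.
#' @param valid Optional logical vector of analysable voxels; defaults to
#'   the conjunction of the two stacks' masks.
#' @return Object of class `tmap`: list with `t` (matrix, NA outside the
#'   valid mask), `valid`, `n_event`, `n_nonevent`, `dim`.
#' @export
welch_tmap <- function(event, nonevent, valid = NULL) {
  ev <- as_stack(event); ne <- as_stack(nonevent)
  if (ncol(ev$X) != ncol(ne$X)) stop("groups must share the voxel grid")
  if (nrow(ev$X) < 2L || nrow(ne$X) < 2L)
    stop("both groups need at least 2 patients for a variance")
  if (is.null(valid)) valid <- ev$valid & ne$valid
  if (!any(valid)) stop("no voxel is analysable in both groups")
  dm <- if (all(ev$dim == ne$dim) && prod(ev$dim) == ncol(ev$X)) ev$dim
        else c(1L, ncol(ev$X))
  X <- rbind(ev$X, ne$X)
  n1 <- nrow(ev$X)
  P <- matrix(0, 1, nrow(X)); P[1, seq_len(n1)] <- 1
  tv <- as.vector(welch_perm_stats(X, P, n1))
  valid <- valid & is.finite(tv)
  tv[!valid] <- NA_real_
  structure(list(t = restore_dim(tv, dm), valid = restore_dim(valid, dm),
                 n_event = n1, n_nonevent = nrow(ne$X), dim = dm,
                 statistic = "welch"),
            class = "tmap")
}

#' @export
print.tmap <- function(x, ...) {
  cat(sprintf("<tmap> %s, %d x %d, %d valid voxels, groups %d/%d, t range %.2f..%.2f\n",
              x$statistic, x$dim[1], x$dim[2], sum(x$valid),
              x$n_event, x$n_nonevent,
              min(x$t, na.rm = TRUE), max(x$t, na.rm = TRUE)))
  invisible(x)
}

#' Voxel-wise Mann-Whitney U map
#'
#' Rank-sum alternative to [welch_tmap()]. Reports the raw U statistic of
#' the event group and its tie-corrected standardized value z, so the
#' same permutation Tmax machinery applies to either statistic. Positive
#' z means events ranked higher (received more dose).
#'
#' @inheritParams welch_tmap
#' @return Object of class `tmap` with elements `t` (standardized z) and
#'   `U` (raw U of the event group).
#' @export
mannwhitney_map <- function(event, nonevent, valid = NULL) {
  ev <- as_stack(event); ne <- as_stack(nonevent)
  if (ncol(ev$X) != ncol(ne$X)) stop("groups must share the voxel grid")
  if (nrow(ev$X) < 2L || nrow(ne$X) < 2L)
    stop("both groups need at least 2 patients")
  if (is.null(valid)) valid <- ev$valid & ne$valid
  if (!any(valid)) stop("no voxel is analysable in both groups")
  dm <- if (all(ev$dim == ne$dim) && prod(ev$dim) == ncol(ev$X)) ev$dim
        else c(1L, ncol(ev$X))
  X <- rbind(ev$X, ne$X)
  n1 <- nrow(ev$X)
  P <- matrix(0, 1, nrow(X)); P[1, seq_len(n1)] <- 1
  st <- mw_perm_stats(X, P, n1)
  z <- as.vector(st$z); U <- as.vector(st$U)
  valid <- valid & is.finite(z)
  z[!valid] <- NA_real_; U[!valid] <- NA_real_
  structure(list(t = restore_dim(z, dm), U = restore_dim(U, dm),
                 valid = restore_dim(valid, dm),
                 n_event = n1, n_nonevent = nrow(ne$X), dim = dm,
                 statistic = "mannwhitney"),
            class = "tmap")
}

#' Shapiro-Wilk normality screen of one group's voxel distributions
#'
#' Tests, per voxel, whether the group's dose values across patients are
#' compatible with a normal distribution. The screen is reported, never
#' enforced: the Welch map is computed regardless, on central-limit
#' grounds for the group sizes used here. Voxels with (near-)constant
#' values have no defined test and are flagged non-analysable.
#'
#' @param group Patient-by-voxel matrix (or stack/list of maps), at least
#'   3 rows. Sample sizes above 5000 are not supported by the test.
#' @param alpha Significance level of the screen (default 0.05).
#' @return List: `p` (per-voxel p-value, NA where not analysable),
#'   `fail` (logical, p < alpha), `frac_failing` (share of analysable
#'   voxels failing), `n_tested`.
#' @export
shapiro_screen <- function(group, alpha = 0.05) {
  g <- as_stack(group)
  n <- nrow(g$X)
  if (n < 3L) {
    warning("need at least 3 observations; normality screen skipped")
    return(list(p = rep(NA_real_, ncol(g$X)), fail = rep(NA, ncol(g$X)),
                frac_failing = NA_real_, n_tested = 0L))
  }
  p <- rep(NA_real_, ncol(g$X))
  for (j in which(g$valid)) {
    x <- g$X[, j]
    if (diff(range(x)) < .Machine$double.eps^0.5 * max(1, abs(x[1]))) next
    p[j] <- tryCatch(stats::shapiro.test(x)$p.value,
                     error = function(e) NA_real_)
  }
  tested <- !is.na(p)
  list(p = p, fail = ifelse(tested, p < alpha, NA),
       frac_failing = if (any(tested)) mean(p[tested] < alpha) else NA_real_,
       n_tested = sum(tested))
}

# ---- permutation Tmax ----------------------------------------------------

#' Permutation Tmax significance thresholds for a voxel-wise map
#'
#' Family-wise error control by the maximum-statistic permutation method:
#' outcome labels are reshuffled (preserving the observed event count),
#' the statistic map recomputed for each permutation, and the per-
#' permutation maximum (Tmax) and minimum (Tmin) over valid voxels
#' collected. The upper significance threshold is the nearest-rank
#' `percentile`-th percentile of the Tmax sample (the 950th of 1000
#' sorted values at the default); the lower threshold is the symmetric
#' nearest-rank percentile of the Tmin sample. Observed voxels at or
#' beyond a threshold form the significance masks.
#'
#' Both tails are computed; `tails` selects which masks are considered
#' "significant" by downstream reporting. The default `"both"` reflects
#' that high-risk subregions can appear as positive (events dosed higher)
#' or negative (events dosed lower) associations.
#'
#' @param stack Patient-by-voxel stack ([dsm_stack()], matrix, or list of
#'   [dsm()]).
#' @param labels 0/1 event labels (or a dichotomization data frame), one
#'   per patient; `NA` labels are excluded.
#' @param statistic `"welch"` or `"mannwhitney"` (standardized U).
#' @param n_iterations Number of permutations (>= 100; default 1000).
#' @param percentile Percentile of the Tmax distribution used as the
#'   threshold (default 95, i.e. family-wise alpha 0.05 per tail).
#' @param tails `"both"`, `"upper"` or `"lower"`.
#' @param seed Integer seed controlling the permutations only.
#' @return Object of class `perm_result`: observed `tmap`, `tmax_samples`,
#'   `tmin_samples`, `threshold_upper`, `threshold_lower`, `sig_mask_high`,
#'   `sig_mask_low`, `sig_mask` (per `tails`), plus the call parameters.
#' @export
permutation_tmax <- function(stack, labels,
                             statistic = c("welch", "mannwhitney"),
                             n_iterations = 1000L, percentile = 95,
                             tails = c("both", "upper", "lower"),
                             seed = 1L) {
  statistic <- match.arg(statistic); tails <- match.arg(tails)
  if (n_iterations < 100L) stop("`n_iterations` must be at least 100")
  if (percentile <= 0 || percentile >= 100) stop("`percentile` must be in (0, 100)")
  stack <- as_stack(stack)
  ev <- if (is.data.frame(labels)) labels$event else labels
  if (length(ev) != nrow(stack$X)) stop("one label per patient required")
  keep <- !is.na(ev)
  X <- stack$X[keep, , drop = FALSE]
  ev <- ev[keep]
  n <- nrow(X); n1 <- sum(ev == 1)
  if (n1 < 2L || n - n1 < 2L)
    stop("both groups need at least 2 patients before permuting")
  dm <- if (prod(stack$dim) == ncol(X)) stack$dim else c(1L, ncol(X))

  # observed map (groups wrapped as stacks so the 2D shape survives)
  mk <- function(rows) structure(
    list(X = X[rows, , drop = FALSE], valid = stack$valid, dim = dm,
         organ = stack$organ, dose_kind = stack$dose_kind),
    class = "dsm_stack")
  obs <- if (statistic == "welch") {
    welch_tmap(mk(ev == 1), mk(ev == 0))
  } else {
    mannwhitney_map(mk(ev == 1), mk(ev == 0))
  }

  # label reshuffles preserving the event count
  set.seed(as.integer(seed))
  P <- matrix(0, n_iterations, n)
  for (b in seq_len(n_iterations))
    P[b, sample.int(n, n1)] <- 1
  reord <- c(which(ev == 1), which(ev == 0))  # match observed map's row order
  Xp <- X[reord, , drop = FALSE]
  Pp <- P[, reord, drop = FALSE]
  stat_mat <- if (statistic == "welch") welch_perm_stats(Xp, Pp, n1)
              else mw_perm_stats(Xp, Pp, n1)$z
  vmask <- as.vector(obs$valid)
  stat_mat[, !vmask] <- NA_real_
  tmax <- row_max(stat_mat); tmin <- row_min(stat_mat)

  # nearest rank; round before ceiling so e.g. (1 - 95/100) * 200, which
  # floating point puts a hair above 10, still yields rank 10
  k_up <- ceiling(round(percentile / 100 * n_iterations, 8))
  k_lo <- ceiling(round((1 - percentile / 100) * n_iterations, 8))
  thr_up <- sort(tmax)[k_up]
  thr_lo <- sort(tmin)[k_lo]
  tv <- obs$t
  sig_high <- obs$valid & !is.na(tv) & tv >= thr_up
  sig_low <- obs$valid & !is.na(tv) & tv <= thr_lo
  sig <- switch(tails, both = sig_high | sig_low, upper = sig_high,
                lower = sig_low)
  structure(list(observed = obs, tmax_samples = tmax, tmin_samples = tmin,
                 threshold_upper = thr_up, threshold_lower = thr_lo,
                 sig_mask_high = sig_high, sig_mask_low = sig_low,
                 sig_mask = sig, n_iterations = n_iterations,
                 percentile = percentile, tails = tails, seed = seed,
                 statistic = statistic, dim = dm),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf(paste0("<perm_result> %s, %d permutations, %gth percentile (%s tails)\n",
                     "  thresholds: upper %.3f, lower %.3f; significant voxels: %d high, %d low\n"),
              x$statistic, x$n_iterations, x$percentile, x$tails,
              x$threshold_upper, x$threshold_lower,
              sum(x$sig_mask_high), sum(x$sig_mask_low)))
  invisible(x)
}

#' Dice similarity coefficient between two binary masks
#'
#' \eqn{DSC = 2 |A \cap B| / (|A| + |B|)}. When both masks are empty the
#' coefficient is defined as 0, matching the reporting convention
#' "DSC = 0.0" when a method finds no significant voxels.
#'
#' @param mask_a,mask_b Logical matrices of identical shape.
#' @return Object of class `dsc_result`: `dsc`, `n_a`, `n_b`,
#'   `n_intersection`.
#' @export
dsc <- function(mask_a, mask_b) {
  if (!is.logical(mask_a) || !is.logical(mask_b) ||
      !all(dim(mask_a) == dim(mask_b)))
    stop("masks must be logical arrays of identical shape")
  na <- sum(mask_a); nb <- sum(mask_b); ni <- sum(mask_a & mask_b)
  val <- if (na + nb == 0) 0 else 2 * ni / (na + nb)
  structure(list(dsc = val, n_a = na, n_b = nb, n_intersection = ni),
            class = "dsc_result")
}

#' @export
print.dsc_result <- function(x, ...) {
  cat(sprintf("<dsc_result> DSC = %.3f (|A| = %d, |B| = %d, overlap = %d)\n",
              x$dsc, x$n_a, x$n_b, x$n_intersection))
  invisible(x)
}

#' Count significant voxels in a mask
#'
#' @param mask Logical matrix (typically a significance mask).
#' @return Integer count of `TRUE` voxels.
#' @export
count_significant <- function(mask) {
  stopifnot(is.logical(mask))
  sum(mask)
}
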