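# Visualisation: mean-dose map with the significant subregion contoured,
# axes annotated from the documented anatomical convention table.

#' Plot a dose-response map
#'
#' Draws the cohort mean dose-surface map (yellow = highest dose, black =
#' lowest) and overlays the boundary of the significant subregion from a
#' permutation result. Row/column axis labels come from [dsm_axes()].
#'
#' @param perm A [permutation_tmax()] result on a 2D map.
#' @param mean_dose Matrix of per-voxel mean dose to use as background;
#'   default: event and non-event pooled mean is not stored in `perm`,
#'   so this argument is required for a dose background. Pass `NULL` to
#'   colour by the observed statistic instead.
#' @param organ Organ for axis annotation (`"bladder"` or `"rectum"`).
#' @param main Plot title.
#' @param contour_col Colour of the significance contour.
#' @return Invisibly, the matrix that was plotted.
#' @export
plot_drm <- function(perm, mean_dose = NULL,
                     organ = c("bladder", "rectum"),
                     main = "dose-response map", contour_col = "red") {
  stopifnot(inherits(perm, "perm_result"))
  organ <- match.arg(organ)
  bg <- if (is.null(mean_dose)) perm$observed$t else mean_dose
  stopifnot(is.matrix(bg))
  nr <- nrow(bg); nc <- ncol(bg)
  pal <- grDevices::colorRampPalette(c("black", "darkred", "orange",
                                       "yellow"))(64)
  # image() draws x along rows; transpose and flip so row 1 is at the top
  graphics::image(x = seq_len(nc), y = seq_len(nr),
                  z = t(bg[nr:1, , drop = FALSE]),
                  col = pal, xlab = "", ylab = "", axes = FALSE, main = main,
                  useRaster = TRUE)
  ax <- dsm_axes(organ)
  if (organ == "bladder") {
    lm <- ax$landmarks
    graphics::axis(1, at = lm, labels = c("A", "L", "P", "R"))
    graphics::axis(2, at = c(nr, 1), labels = c("S", "I"))
  } else {
    graphics::axis(1, at = c(1, 23, 45.5, 68, 90),
                   labels = c("P", "R", "A", "L", "P"))
    graphics::axis(2, at = c(1, nr), labels = c("I", "S"))
  }
  graphics::box()
  m <- perm$sig_mask
  if (any(m)) {
    graphics::contour(x = seq_len(nc), y = seq_len(nr),
                      z = t(m[nr:1, , drop = FALSE]) * 1,
                      levels = 0.5, add = TRUE, drawlabels = FALSE,
                      col = contour_col, lwd = 2)
  }
  invisible(bg)
}
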