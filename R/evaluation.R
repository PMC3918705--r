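#' Average perpendicular distance between contours
#'
#' Mean, over `n` arc-length samples of the predicted contour, of the
#' closest-point distance to the reference polyline, scaled to mm by the
#' pixel spacing.  One-directional (pred to ref) by default; the symmetric
#' variant averages both directions.
#'
#' @param pred,ref `lv_contour`s (same pixel spacing).
#' @param n number of samples on `pred` (default 128).
#' @param symmetric also average the ref-to-pred direction.
#' @return non-negative distance in mm.
#' @export
apd <- function(pred, ref, n = 128, symmetric = FALSE) {
  stopifnot(inherits(pred, "lv_contour"), inherits(ref, "lv_contour"))
  if (abs(pred$pixel_spacing - ref$pixel_spacing) > 1e-12) {
    warning("contours have different pixel spacings; using pred's")
  }
  one_way <- function(p, r) {
    s <- resample_closed(p, n)$points
    mean(dist_to_polyline(s, r$points))
  }
  d <- one_way(pred, ref)
  if (symmetric) d <- (d + one_way(ref, pred)) / 2
  d * pred$pixel_spacing
}

#' Gold-standard contour from three manual tracings
#'
#' Averages three expert contours with the same iterated
#' normal-intersection procedure used for detector fusion (M = 3).
#'
#' @param c1,c2,c3 `lv_contour`s (arbitrary sizes; resampled to `n`).
#' @param n common resampling size (default 128).
#' @param ... passed to [fuse_contours()].
#' @return the averaged `lv_contour`.
#' @export
gold_standard <- function(c1, c2, c3, n = 128, ...) {
  cs <- lapply(list(c1, c2, c3), resample_closed, n = n)
  fuse_contours(cs, ...)$contour
}

#' Area-based ejection fraction
#'
#' `100 * (area_ed - area_es) / area_ed`: the fractional reduction of
#' cavity area from end-diastole to end-systole, in percent.  Area-based
#' because the tracker works on a single 2D plane; no area-length volume
#' model is applied.
#'
#' @param area_ed end-diastolic area (> 0).
#' @param area_es end-systolic area (warns when larger than `area_ed`).
#' @return percent.
#' @export
ejection_fraction <- function(area_ed, area_es) {
  if (area_ed <= 0) stop("end-diastolic area must be positive")
  if (area_es > area_ed || area_es <= 0) {
    warning("expected 0 < area_es <= area_ed")
  }
  100 * (area_ed - area_es) / area_ed
}

#' Bland-Altman agreement statistics
#'
#' Differences `d = x - y`; bias is `mean(d)` and the limits of agreement
#' are `bias +/- 1.96 * sd(d)` (sample standard deviation).
#'
#' @param x,y paired measurement vectors of equal length (>= 2).
#' @return list with `bias`, `lower`, `upper` (limits of agreement),
#'   `sd` of the differences.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, lower = bias - 1.96 * s, upper = bias + 1.96 * s,
       sd = s)
}
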