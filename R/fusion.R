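#' Point-wise average of corresponded contours
#'
#' Arithmetic mean of M contours that share the same size and anchoring
#' convention (see [resample_closed()]), point by point.
#'
#' @param contours list of `lv_contour`, all with the same number of
#'   points.
#' @return an `lv_contour`.
#' @export
average_contours <- function(contours) {
  stopifnot(length(contours) >= 1)
  ns <- vapply(contours, function(cc) nrow(cc$points), integer(1))
  if (length(unique(ns)) != 1) stop("contours have mismatched sizes")
  pts <- Reduce(`+`, lapply(contours, `[[`, "points")) / length(contours)
  contour(pts, pixel_spacing = contours[[1]]$pixel_spacing,
          validate = FALSE)
}

#' Iterated normal-intersection averaging of contours
#'
#' The averaging fusion procedure: (1) average the corresponded contours
#' point-wise; (2) at each averaged point compute the outward scatter-matrix
#' normal ([contour_normals()]); (3) intersect the normal line with each
#' input contour, taking the intersection nearest the averaged point;
#' (4) re-average the intersection points.  Repeat until the maximum point
#' displacement between successive averaged contours falls below `tol` or
#' `max_iter` is reached.  The normals are always re-intersected with the
#' ORIGINAL contours.  When a normal misses a contour the previous
#' correspondence point for that index is kept (counted in `fallbacks`).
#'
#' @param contours list of M `lv_contour`s of equal size (M = 2 for
#'   BM + snake fusion, M = 3 for the gold standard).
#' @param tol convergence tolerance in pixels on the maximum point
#'   displacement (default 0.05).
#' @param max_iter maximum iterations (default 20).
#' @param window scatter-matrix half-width for the normals (default 3).
#' @return list: `contour` (the fused `lv_contour`), `iterations`,
#'   `displacements` (per-iteration maximum displacement), `fallbacks`
#'   (count of missed intersections).
#' @export
fuse_contours <- function(contours, tol = 0.05, max_iter = 20, window = 3) {
  M <- length(contours)
  stopifnot(M >= 2)
  ns <- vapply(contours, function(cc) nrow(cc$points), integer(1))
  if (length(unique(ns)) != 1) stop("contours have mismatched sizes")
  n <- ns[1]
  avg <- average_contours(contours)
  corr <- lapply(contours, `[[`, "points")   # fallback correspondences
  disps <- numeric(0)
  fallbacks <- 0L
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    nrm <- contour_normals(avg, window = window)
    for (j in seq_len(M)) {
      hit <- ray_hits(avg$points, nrm, contours[[j]]$points)
      miss <- !hit$found
      fallbacks <- fallbacks + sum(miss)
      corr[[j]] <- cbind(ifelse(miss, corr[[j]][, 1], hit$px),
                         ifelse(miss, corr[[j]][, 2], hit$py))
    }
    new_pts <- Reduce(`+`, corr) / M
    disp <- max(sqrt(rowSums((new_pts - avg$points)^2)))
    disps <- c(disps, disp)
    avg <- contour(new_pts, pixel_spacing = avg$pixel_spacing,
                   validate = FALSE)
    if (disp < tol) break
  }
  list(contour = avg, iterations = iter, displacements = disps,
       fallbacks = fallbacks)
}

#' Fuse two contours (BM + snake)
#'
#' Two-contour wrapper around [fuse_contours()].
#'
#' @param a,b `lv_contour`s of equal size, resampled with the shared
#'   anchoring convention.
#' @inheritParams fuse_contours
#' @return list with `contour` and `iterations` (plus the diagnostics of
#'   [fuse_contours()]).
#' @export
fuse <- function(a, b, tol = 0.05, max_iter = 20, window = 3) {
  fuse_contours(list(a, b), tol = tol, max_iter = max_iter, window = window)
}
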