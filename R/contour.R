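#' Closed endocardial contour
#'
#' A contour is the shared currency of every module in lvtrack: an ordered,
#' closed, simple polyline of 2D points in pixel coordinates.  On
#' construction the orientation is normalised to anticlockwise (positive
#' shoelace signed area with x right / y "up" in the algebraic sense; on an
#' image displayed with y increasing downwards this draws clockwise, which is
#' irrelevant — all geometry below is internally consistent).  The point of
#' maximum y is the apex under the apex-down convention used throughout.
#'
#' @param points numeric n x 2 matrix (or data frame with columns `x`, `y`)
#'   of vertex positions in pixels.  A repeated closing point is dropped.
#' @param pixel_spacing mm per pixel, used when areas/distances are requested
#'   in physical units.  Default 1.
#' @param validate check the contour invariants (at least 4 points, no
#'   repeated consecutive points, simple polygon).  Internal callers that
#'   construct contours from already-valid geometry may skip this.
#' @return an object of class `lv_contour` with elements `points`
#'   (n x 2 matrix, columns `x`, `y`) and `pixel_spacing`.
#' @export
contour <- function(points, pixel_spacing = 1.0, validate = TRUE) {
  if (is.data.frame(points)) {
    if (all(c("x", "y") %in% names(points))) {
      points <- cbind(points$x, points$y)
    } else {
      points <- as.matrix(points[, 1:2])
    }
  }
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("contour points must be an n x 2 matrix")
  storage.mode(points) <- "double"
  if (any(!is.finite(points))) stop("contour points must be finite")
  n <- nrow(points)
  if (n >= 2 && all(points[1, ] == points[n, ])) {
    points <- points[-n, , drop = FALSE]
    n <- n - 1
  }
  if (validate) {
    if (n < 4) stop("a contour needs at least 4 points")
    nxt <- c(2:n, 1)
    seglen <- sqrt(rowSums((points[nxt, , drop = FALSE] - points)^2))
    if (any(seglen == 0)) stop("contour has repeated consecutive points")
  }
  sa <- signed_area(points)
  if (validate && sa == 0) stop("degenerate contour: zero signed area")
  if (sa < 0) points <- points[rev(seq_len(nrow(points))), , drop = FALSE]
  if (validate && !is_simple_polygon(points)) {
    stop("contour is self-intersecting")
  }
  colnames(points) <- c("x", "y")
  rownames(points) <- NULL
  structure(list(points = points, pixel_spacing = as.numeric(pixel_spacing)),
            class = "lv_contour")
}

#' @export
print.lv_contour <- function(x, ...) {
  cat(sprintf(
    "lv_contour: %d points, perimeter %.2f px, area %.2f px^2, spacing %g mm/px\n",
    nrow(x$points), perimeter(x), polygon_area(x), x$pixel_spacing))
  invisible(x)
}

as_points <- function(x) {
  if (inherits(x, "lv_contour")) x$points else x
}

# shoelace signed area; positive for anticlockwise order
signed_area <- function(pts) {
  pts <- as_points(pts)
  n <- nrow(pts)
  nxt <- c(2:n, 1)
  sum(pts[, 1] * pts[nxt, 2] - pts[nxt, 1] * pts[, 2]) / 2
}

#' Area enclosed by a contour
#'
#' Shoelace formula on the anticlockwise polygon; always positive for a
#' valid contour.
#'
#' @param contour an [contour()] object.
#' @param units `"px"` (pixel^2, default) or `"mm"` (scaled by
#'   `pixel_spacing^2`).
#' @return positive scalar area.
#' @export
polygon_area <- function(contour, units = c("px", "mm")) {
  units <- match.arg(units)
  a <- abs(signed_area(contour))
  if (units == "mm") a <- a * contour$pixel_spacing^2
  a
}

#' Perimeter of a closed contour
#' @inheritParams polygon_area
#' @return positive scalar length (px or mm).
#' @export
perimeter <- function(contour, units = c("px", "mm")) {
  units <- match.arg(units)
  pts <- as_points(contour)
  n <- nrow(pts)
  p <- sum(sqrt(rowSums((pts[c(2:n, 1), , drop = FALSE] - pts)^2)))
  if (units == "mm") p <- p * contour$pixel_spacing
  p
}

#' Area centroid of a closed contour
#' @param contour an [contour()] object or n x 2 point matrix.
#' @return length-2 numeric (x, y) in pixels.
#' @export
polygon_centroid <- function(contour) {
  pts <- as_points(contour)
  n <- nrow(pts)
  nxt <- c(2:n, 1)
  cross <- pts[, 1] * pts[nxt, 2] - pts[nxt, 1] * pts[, 2]
  a <- sum(cross) / 2
  if (a == 0) return(colMeans(pts))
  cx <- sum((pts[, 1] + pts[nxt, 1]) * cross) / (6 * a)
  cy <- sum((pts[, 2] + pts[nxt, 2]) * cross) / (6 * a)
  c(cx, cy)
}

# O(n^2) pairwise proper-intersection test between non-adjacent edges
is_simple_polygon <- function(pts) {
  pts <- as_points(pts)
  n <- nrow(pts)
  if (n < 3) return(FALSE)
  nxt <- c(2:n, 1)
  p <- pts
  q <- pts[nxt, , drop = FALSE]
  cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2)) {
    # candidate edges j strictly after i, not adjacent (wrap adjacency for i=1)
    j <- (i + 2):n
    if (i == 1) j <- j[j != n]
    if (!length(j)) next
    rix <- q[i, 1] - p[i, 1]; riy <- q[i, 2] - p[i, 2]
    sjx <- q[j, 1] - p[j, 1]; sjy <- q[j, 2] - p[j, 2]
    denom <- cross2(rix, riy, sjx, sjy)
    dx <- p[j, 1] - p[i, 1]; dy <- p[j, 2] - p[i, 2]
    t <- cross2(dx, dy, sjx, sjy)
    u <- cross2(dx, dy, rix, riy)
    ok <- denom != 0
    t <- t / ifelse(ok, denom, 1)
    u <- u / ifelse(ok, denom, 1)
    hit <- ok & t > 0 & t < 1 & u > 0 & u < 1
    # collinear overlap: denom == 0 and points of j on line of i, overlapping
    col <- !ok & cross2(dx, dy, rix, riy) == 0
    if (any(col)) {
      for (jj in j[col]) {
        ti0 <- sum((pts[jj, ] - p[i, ]) * c(rix, riy)) / sum(c(rix, riy)^2)
        ti1 <- sum((q[jj, ] - p[i, ]) * c(rix, riy)) / sum(c(rix, riy)^2)
        lo <- min(ti0, ti1); hi <- max(ti0, ti1)
        if (hi > 0 && lo < 1) return(FALSE)
      }
    }
    if (any(hit)) return(FALSE)
  }
  TRUE
}

#' Resample a closed contour uniformly by arc length
#'
#' The output starts at the apex (point of maximum y under the apex-down
#' convention) and runs anticlockwise, which is the anchoring that gives
#' resampled contours of the same shape a one-to-one point correspondence —
#' the correspondence assumed by the fusion and dynamics modules.
#'
#' @param contour an [contour()] object.
#' @param n number of output points, at least 4.
#' @return an `lv_contour` with `n` uniformly spaced points.
#' @export
resample_closed <- function(contour, n) {
  stopifnot(inherits(contour, "lv_contour"))
  if (n < 4) stop("n must be at least 4")
  pts <- contour$points
  m <- nrow(pts)
  # anchor at the vertex of maximum y (ties: first)
  i0 <- which.max(pts[, 2])
  pts <- pts[c(i0:m, seq_len(i0 - 1)), , drop = FALSE]
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  L <- sum(seg)
  if (L <= 0) stop("degenerate contour: zero perimeter")
  s <- c(0, cumsum(seg))
  targets <- seq(0, L, length.out = n + 1)[seq_len(n)]
  idx <- findInterval(targets, s, rightmost.closed = TRUE)
  idx[idx > m] <- m
  frac <- (targets - s[idx]) / seg[idx]
  frac[!is.finite(frac)] <- 0
  out <- closed[idx, , drop = FALSE] +
    frac * (closed[idx + 1, , drop = FALSE] - closed[idx, , drop = FALSE])
  contour(out, pixel_spacing = contour$pixel_spacing, validate = FALSE)
}

# uniform arc-length resample keeping the current start point (no apex
# re-anchoring); used internally where point identity must persist
resample_keep_start <- function(pts, n) {
  m <- nrow(pts)
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  L <- sum(seg)
  if (L <= 0) stop("degenerate contour: zero perimeter")
  s <- c(0, cumsum(seg))
  targets <- seq(0, L, length.out = n + 1)[seq_len(n)]
  idx <- findInterval(targets, s, rightmost.closed = TRUE)
  idx[idx > m] <- m
  frac <- (targets - s[idx]) / seg[idx]
  frac[!is.finite(frac)] <- 0
  closed[idx, , drop = FALSE] +
    frac * (closed[idx + 1, , drop = FALSE] - closed[idx, , drop = FALSE])
}

#' Read / write contours
#'
#' The CSV interchange format has a header `x,y` and one point per row in
#' pixel coordinates, without a repeated closing point.  The JSON format
#' holds `points` (array of `[x, y]`) and `pixel_spacing_mm`.
#'
#' @param path file path.
#' @param pixel_spacing mm per pixel recorded on the contour read from CSV
#'   (the CSV itself carries no spacing).
#' @return [read_contour_csv()] and [read_contour_json()] return an
#'   `lv_contour`; the writers return the path invisibly.
#' @export
read_contour_csv <- function(path, pixel_spacing = 1.0) {
  df <- utils::read.csv(path)
  contour(df, pixel_spacing = pixel_spacing)
}

#' @rdname read_contour_csv
#' @param contour an [contour()] object to write.
#' @export
write_contour_csv <- function(contour, path) {
  utils::write.csv(as.data.frame(contour$points), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_contour_csv
#' @export
read_contour_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  sp <- if (!is.null(obj$pixel_spacing_mm)) obj$pixel_spacing_mm else 1.0
  contour(obj$points, pixel_spacing = sp)
}

#' @rdname read_contour_csv
#' @export
write_contour_json <- function(contour, path) {
  jsonlite::write_json(
    list(points = unname(contour$points),
         pixel_spacing_mm = contour$pixel_spacing),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
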