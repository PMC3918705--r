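#' Scatter matrix of a point neighbourhood
#'
#' The 2 x 2 scatter matrix of a set of points, normalised by the total
#' variance so that its trace is 1.  Its eigenvector for the larger
#' eigenvalue is the local tangent direction of a curve sampled by the
#' points; the eigenvector for the smaller eigenvalue is the local normal.
#' The closed-form 2 x 2 eigendecomposition is used.
#'
#' @param pts k x 2 matrix of points (k >= 2, not all identical).
#' @return an object of class `lv_scatter`: entries `a11`, `a12`, `a22`
#'   (with `a11 + a22 == 1`), eigenvalues `alpha_M >= alpha_m`
#'   (`alpha_M + alpha_m == 1`) and unit eigenvectors `aM` (tangent) and
#'   `am` (normal), mutually orthogonal.
#' @export
scatter_matrix <- function(pts) {
  pts <- as_points(pts)
  dx <- pts[, 1] - mean(pts[, 1])
  dy <- pts[, 2] - mean(pts[, 2])
  tot <- sum(dx^2 + dy^2)
  if (tot <= 0) stop("degenerate neighbourhood: all points identical")
  a11 <- sum(dx * dx) / tot
  a12 <- sum(dx * dy) / tot
  a22 <- sum(dy * dy) / tot
  e <- eig2_sym(a11, a12, a22)
  structure(list(a11 = a11, a12 = a12, a22 = a22,
                 alpha_M = e$lmax, alpha_m = e$lmin,
                 aM = e$vmax, am = e$vmin),
            class = "lv_scatter")
}

# closed-form eigendecomposition of [[a11, a12], [a12, a22]].
# When a12 == 0 the eigenvectors are the coordinate axes; the generic
# formula's denominator vanishes there, so that case is returned directly.
eig2_sym <- function(a11, a12, a22) {
  mean2 <- (a11 + a22) / 2
  disc <- sqrt(((a11 - a22) / 2)^2 + a12^2)
  lmax <- mean2 + disc
  lmin <- mean2 - disc
  if (a12 == 0 || disc == 0) {
    if (a11 >= a22) {
      vmax <- c(1, 0); vmin <- c(0, 1)
    } else {
      vmax <- c(0, 1); vmin <- c(1, 0)
    }
  } else {
    # two equivalent eigenvector forms; use the better-conditioned one
    pick <- function(l) {
      v1 <- c(a12, l - a11)
      v2 <- c(l - a22, a12)
      v <- if (sum(v1^2) >= sum(v2^2)) v1 else v2
      v / sqrt(sum(v^2))
    }
    vmax <- pick(lmax)
    vmin <- pick(lmin)
  }
  list(lmax = lmax, lmin = lmin, vmax = vmax, vmin = vmin)
}

#' Outward unit normal at a contour point
#'
#' Builds the normalised scatter matrix of the `2*window + 1` point
#' neighbourhood centred at `index` and returns the eigenvector of the
#' smaller eigenvalue (the direction of least spread, i.e. the curve
#' normal), oriented outward: positive dot product with the vector from the
#' contour's area centroid to the point.
#'
#' @param contour an [contour()] object.
#' @param index point index (1-based).
#' @param window neighbourhood half-width in points (default 3);
#'   `2*window + 1` must not exceed the number of points.
#' @return unit length-2 numeric vector.
#' @export
local_normal <- function(contour, index, window = 3) {
  pts <- as_points(contour)
  n <- nrow(pts)
  if (window < 1) stop("window must be >= 1")
  if (2 * window + 1 > n) stop("window too large for contour size")
  idx <- ((index - 1 + (-window:window)) %% n) + 1
  sm <- scatter_matrix(pts[idx, , drop = FALSE])
  v <- sm$am
  ctr <- polygon_centroid(contour)
  out <- pts[index, ] - ctr
  if (sum(v * out) < 0) v <- -v
  v
}

#' Outward unit normals at every contour point
#'
#' Vectorised version of [local_normal()] over all points; the workhorse of
#' the fusion loop.
#'
#' @inheritParams local_normal
#' @return n x 2 matrix of outward unit normals.
#' @export
contour_normals <- function(contour, window = 3) {
  pts <- as_points(contour)
  n <- nrow(pts)
  if (2 * window + 1 > n) stop("window too large for contour size")
  k <- 2 * window + 1
  idx <- (outer(seq_len(n) - 1, -window:window, "+") %% n) + 1
  X <- matrix(pts[idx, 1], n, k)
  Y <- matrix(pts[idx, 2], n, k)
  mx <- rowMeans(X)
  my <- rowMeans(Y)
  dx <- X - mx
  dy <- Y - my
  sxx <- rowSums(dx * dx)
  sxy <- rowSums(dx * dy)
  syy <- rowSums(dy * dy)
  tot <- sxx + syy
  if (any(tot <= 0)) stop("degenerate neighbourhood: all points identical")
  a11 <- sxx / tot
  a12 <- sxy / tot
  a22 <- syy / tot
  disc <- sqrt(((a11 - a22) / 2)^2 + a12^2)
  lmin <- (a11 + a22) / 2 - disc
  # two equivalent eigenvector forms; per point use the better-conditioned
  v1x <- a12;        v1y <- lmin - a11
  v2x <- lmin - a22; v2y <- a12
  use1 <- v1x^2 + v1y^2 >= v2x^2 + v2y^2
  vx <- ifelse(use1, v1x, v2x)
  vy <- ifelse(use1, v1y, v2y)
  # a12 == 0: axis-aligned normal (along the smaller-variance axis)
  degen <- a12 == 0 | disc == 0
  vx[degen] <- ifelse(a11[degen] >= a22[degen], 0, 1)
  vy[degen] <- ifelse(a11[degen] >= a22[degen], 1, 0)
  len <- sqrt(vx^2 + vy^2)
  vx <- vx / len
  vy <- vy / len
  ctr <- polygon_centroid(contour)
  s <- sign(vx * (pts[, 1] - ctr[1]) + vy * (pts[, 2] - ctr[2]))
  s[s == 0] <- 1
  cbind(vx * s, vy * s)
}

#' Nearest intersection of a line with a closed polyline
#'
#' Intersects the infinite line through `origin` along +/- `direction` with
#' every segment of the contour and returns the intersection point nearest
#' to the origin (smallest |t| where the line is `origin + t * direction`).
#'
#' @param origin length-2 numeric point.
#' @param direction length-2 non-zero direction vector.
#' @param contour an [contour()] object.
#' @return the intersection point (length-2 numeric) with attribute `"t"`
#'   (signed line parameter), or `NULL` when the line misses the contour —
#'   the caller (fusion) treats `NULL` as the signal to fall back.
#' @export
intersect_ray_polyline <- function(origin, direction, contour) {
  if (sum(direction^2) == 0) stop("direction must be non-zero")
  pts <- as_points(contour)
  hit <- ray_hits(matrix(origin, 1), matrix(direction, 1), pts)
  if (!hit$found[1]) return(NULL)
  structure(c(hit$px[1], hit$py[1]), t = hit$t[1])
}

# Vectorised line/polyline nearest intersections for many origins at once.
# origins, dirs: m x 2; pts: contour vertices (n x 2, closed implicitly).
# Returns list(found, px, py, t).
ray_hits <- function(origins, dirs, pts) {
  n <- nrow(pts)
  m <- nrow(origins)
  nxt <- c(2:n, 1)
  px <- pts[, 1]; py <- pts[, 2]
  rx <- pts[nxt, 1] - px; ry <- pts[nxt, 2] - py    # segment vectors (n)
  # broadcast: rows = rays (m), cols = segments (n)
  DX <- matrix(dirs[, 1], m, n)
  DY <- matrix(dirs[, 2], m, n)
  RX <- matrix(rx, m, n, byrow = TRUE)
  RY <- matrix(ry, m, n, byrow = TRUE)
  WX <- matrix(px, m, n, byrow = TRUE) - matrix(origins[, 1], m, n)
  WY <- matrix(py, m, n, byrow = TRUE) - matrix(origins[, 2], m, n)
  denom <- DX * RY - DY * RX          # cross(d, r)
  ok <- abs(denom) > 1e-14
  t <- (WX * RY - WY * RX) / ifelse(ok, denom, 1)   # cross(w, r)/cross(d, r)
  u <- (WX * DY - WY * DX) / ifelse(ok, denom, 1)   # cross(w, d)/cross(d, r)
  eps <- 1e-9
  valid <- ok & u >= -eps & u <= 1 + eps
  t[!valid] <- Inf
  best <- max.col(-abs(t), ties.method = "first")
  tb <- t[cbind(seq_len(m), best)]
  found <- is.finite(tb)
  list(found = found,
       px = origins[, 1] + tb * dirs[, 1],
       py = origins[, 2] + tb * dirs[, 2],
       t = tb)
}
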