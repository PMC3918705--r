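#' Snake (active contour) parameters
#'
#' Weights and numerical settings of the Kass parametric active contour.
#' The total energy is the integral along the curve of the internal term
#' \eqn{\alpha |c'(s)|^2 + \beta |c''(s)|^2} (elasticity and curvature)
#' plus the image term \eqn{E_2 = -\|\nabla I\|^2}, so the snake settles
#' on high-gradient ridges.
#'
#' @param alpha elasticity weight (>= 0), default 0.1.
#' @param beta curvature weight (>= 0), default 0.05.
#' @param step evolution time step (> 0), default 0.5.
#' @param sigma Gaussian pre-smoothing scale in pixels (>= 0), default 2.
#' @param n_iter maximum iterations, default 300.
#' @param ext_weight scale of the image force, default 100.  Images are
#'   unit-intensity (`[0, 1]`), so the squared-gradient energy is of order
#'   1e-2 and its spatial derivative of order 1e-3/px; the default weight
#'   rescales that force to pixel-sized displacements per step (on 8-bit
#'   0..255 data the classical weight of order 1 plays the same role).
#' @return an object of class `lv_snake_params`.
#' @export
snake_params <- function(alpha = 0.1, beta = 0.05, step = 0.5,
                         sigma = 2.0, n_iter = 300, ext_weight = 100) {
  stopifnot(alpha >= 0, beta >= 0, step > 0, sigma >= 0, n_iter >= 0)
  structure(list(alpha = alpha, beta = beta, step = step, sigma = sigma,
                 n_iter = n_iter, ext_weight = ext_weight),
            class = "lv_snake_params")
}

#' Image energy of the active contour
#'
#' Gaussian-smooths the image at scale `sigma`, takes central-difference
#' gradients and returns \eqn{-(I_x^2 + I_y^2)}: everywhere non-positive,
#' most negative on edges.  Sub-pixel values of the map (and of its spatial
#' derivatives, used as the snake's external force) are obtained by
#' bilinear interpolation.
#'
#' @param image numeric matrix in `[0, 1]` (rows = y, columns = x).
#' @param sigma Gaussian pre-smoothing scale in pixels.
#' @return matrix of the same size, `<= 0` everywhere.
#' @export
image_energy <- function(image, sigma = 2.0) {
  if (any(!is.finite(image))) stop("image must be finite-valued")
  sm <- gaussian_blur(image, sigma)
  g <- image_gradient(sm)
  -(g$gx^2 + g$gy^2)
}

# internal-energy evolution matrix (cyclic pentadiagonal) for n points
snake_matrix <- function(n, alpha, beta) {
  idx <- seq_len(n)
  M <- matrix(0, n, n)
  put <- function(off, val) {
    j <- ((idx - 1 + off) %% n) + 1
    M[cbind(idx, j)] <<- M[cbind(idx, j)] + val
  }
  put(0, 2 * alpha + 6 * beta)
  put(-1, -alpha - 4 * beta)
  put(1, -alpha - 4 * beta)
  put(-2, beta)
  put(2, beta)
  M
}

# discrete total snake energy (internal + image) of a point set
snake_energy <- function(pts, emap, alpha, beta) {
  n <- nrow(pts)
  nxt <- c(2:n, 1)
  prv <- c(n, 1:(n - 1))
  d1 <- pts[nxt, , drop = FALSE] - pts
  d2 <- pts[nxt, , drop = FALSE] - 2 * pts + pts[prv, , drop = FALSE]
  sum(alpha * rowSums(d1^2) + beta * rowSums(d2^2)) +
    sum(bilinear_sample(emap, pts[, 1], pts[, 2]))
}

#' Evolve a snake on an image
#'
#' Semi-implicit Kass evolution: the internal (elasticity + curvature)
#' term is treated implicitly through the cyclic pentadiagonal system of
#' its finite differences, the external image force
#' \eqn{-\nabla E_{img}} explicitly, sampled bilinearly at the current
#' points.  Points are redistributed uniformly by arc length every 25
#' iterations to prevent bunching; evolution stops early when the maximum
#' point displacement in an iteration falls below 0.01 px.
#'
#' @param init an [contour()] object inside the image bounds.
#' @param image numeric matrix in `[0, 1]`.
#' @param params an [snake_params()] object.
#' @return the evolved `lv_contour` (same number of points as `init`),
#'   with attributes `"iterations"` (iterations run).
#' @export
evolve_snake <- function(init, image, params = snake_params()) {
  stopifnot(inherits(init, "lv_contour"))
  pts <- init$points
  nr <- nrow(image); nc <- ncol(image)
  if (any(pts[, 1] < 1 | pts[, 1] > nc | pts[, 2] < 1 | pts[, 2] > nr)) {
    stop("initial contour outside image bounds")
  }
  n <- nrow(pts)
  if (params$n_iter == 0) return(init)

  emap <- image_energy(image, params$sigma)
  g <- image_gradient(emap)
  fx <- -g$gx * params$ext_weight
  fy <- -g$gy * params$ext_weight

  Ainv <- solve(diag(n) + params$step * snake_matrix(n, params$alpha,
                                                     params$beta))
  iter_run <- 0L
  for (it in seq_len(params$n_iter)) {
    iter_run <- it
    fxs <- bilinear_sample(fx, pts[, 1], pts[, 2])
    fys <- bilinear_sample(fy, pts[, 1], pts[, 2])
    newx <- Ainv %*% (pts[, 1] + params$step * fxs)
    newy <- Ainv %*% (pts[, 2] + params$step * fys)
    newx <- pmin(nc, pmax(1, newx))
    newy <- pmin(nr, pmax(1, newy))
    disp <- max(abs(cbind(newx, newy) - pts))
    pts <- cbind(as.numeric(newx), as.numeric(newy))
    if (perimeter_of(pts) < 1e-8 || nrow(unique(round(pts, 6))) < 4) {
      stop("snake collapsed below 4 distinct points")
    }
    if (disp < 0.01) break
    if (it %% 25 == 0) pts <- resample_keep_start(pts, n)
  }
  out <- contour(pts, pixel_spacing = init$pixel_spacing, validate = FALSE)
  attr(out, "iterations") <- iter_run
  out
}

perimeter_of <- function(pts) {
  n <- nrow(pts)
  sum(sqrt(rowSums((pts[c(2:n, 1), , drop = FALSE] - pts)^2)))
}
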