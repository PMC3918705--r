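# shared geometric fixtures, built in code

circle_contour <- function(r = 10, n = 64, center = c(0, 0), spacing = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  contour(cbind(center[1] + r * cos(th), center[2] + r * sin(th)),
          pixel_spacing = spacing)
}

ellipse_contour <- function(a = 60, b = 90, n = 128, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  contour(cbind(center[1] + a * cos(th), center[2] + b * sin(th)))
}

unit_square <- function() {
  contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
}

# dark disk on bright ground with the phantom generator's default speckle
# and blur; returns list(image, truth contour)
disk_image <- function(size = 160, center = c(80, 80), r = 30,
                       speckle = 0.5, blur = 1.2, seed = 11) {
  set.seed(seed)
  img <- matrix(0.85, size, size)
  xs <- rep(seq_len(size), each = size)
  ys <- rep(seq_len(size), times = size)
  inside <- (xs - center[1])^2 + (ys - center[2])^2 < r^2
  img[cbind(ys[inside], xs[inside])] <- 0.1
  if (speckle > 0) {
    sh <- 1 / speckle^2
    img <- img * matrix(stats::rgamma(size^2, sh, sh), size, size)
  }
  if (blur > 0) img <- lvtrack:::gaussian_blur(img, blur)
  img <- pmax(pmin(img, 1), 0)
  list(image = img, truth = circle_contour(r, 128, center))
}

# a mildly irregular star-convex polygon (still simple)
blob_contour <- function(seed = 5, n = 48, r = 20, wobble = 0.15,
                         center = c(0, 0)) {
  set.seed(seed)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  amp <- 1 + wobble * sin(3 * th + runif(1, 0, 2 * pi)) +
    0.5 * wobble * sin(5 * th)
  contour(cbind(center[1] + r * amp * cos(th),
                center[2] + r * amp * sin(th)))
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# central finite differences of the total energy density in C (the
# independent oracle for the analytic PK2 stress)
fd_pk2 <- function(F, N, mat, phase, h = 1e-6) {
  C <- t(F) %*% F
  W <- function(v) {
    Cm <- matrix(c(v[1], v[2], v[2], v[3]), 2, 2)
    I1 <- sum(diag(Cm)) + 1
    I4s <- drop(t(N) %*% Cm %*% N)
    I4 <- if (mat$i4_convention == "paper_sqrt") sqrt(I4s) else I4s
    J <- sqrt(det(Cm))
    strain_energy(I1, I4, mat, phase) + mat$kappa / 2 * (J - 1)^2 +
      mat$mu_reg / 2 * (sum(diag(Cm)) - 2) - mat$mu_reg * log(J)
  }
  v <- c(C[1, 1], C[1, 2], C[2, 2])
  d <- function(j, fac) {
    vp <- v; vp[j] <- vp[j] + h
    vm <- v; vm[j] <- vm[j] - h
    fac * (W(vp) - W(vm)) / (2 * h)
  }
  # S_ij = 2 dW/dC_ij with C_ij, C_ji varied together for the off-diagonal
  matrix(c(d(1, 2), d(2, 1), d(2, 1), d(3, 2)), 2, 2)
}

# small assembled LV-phantom mesh shared by FEM tests
phantom_mesh <- function(n_boundary = 40, basal = 0.1) {
  cfg <- phantom_config()
  base <- lvtrack:::phantom_base_contour(cfg)
  assemble_surface(triangulate_region(base, perimeter(base) / n_boundary),
                   basal)
}
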