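#' Quasi-static finite-element solve of the loaded LV domain
#'
#' Total-Lagrangian Newton-Raphson equilibrium on constant-strain
#' triangles: internal forces from the analytic second Piola-Kirchhoff
#' stress ([pk2_stress()]), external load a follower pressure acting on the
#' current configuration of the endocardial SURFACE edges, basal nodes
#' fully fixed.  The tangent stiffness is assembled from central finite
#' differences of the analytic element force (exact follower-load tangent),
#' and the load is applied in increments with step halving on divergence or
#' element inversion.
#'
#' @param mesh an `lv_mesh` after [assemble_surface()] with a non-empty
#'   basal node set (the basal restraint is what suppresses rigid-body
#'   motion).
#' @param params an [material_params()] object.
#' @param pressure signed pressure in kPa; positive acts inward
#'   (systolic contraction), negative outward (diastolic expansion).
#' @param phase `"active"` (systole) or `"passive"` (diastole); defaults to
#'   the sign convention of `pressure` (positive = active).
#' @param max_newton maximum Newton iterations per load step (default 50).
#' @param tol relative residual tolerance (default 1e-8).
#' @param load_steps initial number of load increments (default 10).
#' @param follower apply the pressure on the current (deformed) surface
#'   (default TRUE); FALSE uses a dead load along the reference normals,
#'   kept for diagnostics.
#' @return list with `u` (n x 2 nodal displacement matrix), `converged`,
#'   `iterations` (total Newton iterations), `residual` (final relative
#'   residual), `steps` (number of accepted load increments).
#' @export
solve_deformation <- function(mesh, params, pressure,
                              phase = NULL,
                              max_newton = 50, tol = 1e-8,
                              load_steps = 10, follower = TRUE) {
  stopifnot(inherits(mesh, "lv_mesh"))
  if (is.null(mesh$surface_faces)) {
    stop("mesh has no SURFACE; call assemble_surface() first")
  }
  if (!length(mesh$basal_nodes)) {
    stop("basal node set is empty: the solve needs the basal restraint")
  }
  if (is.null(phase)) phase <- if (pressure >= 0) "active" else "passive"

  pre <- fem_precompute(mesh, params)
  nn <- nrow(mesh$nodes)
  ndof <- 2L * nn
  fixed <- sort(c(2L * mesh$basal_nodes - 1L, 2L * mesh$basal_nodes))
  free <- setdiff(seq_len(ndof), fixed)

  u <- numeric(ndof)
  total_iter <- 0L
  s_done <- 0
  ds <- if (pressure == 0) 1 else 1 / load_steps
  ds_min <- ds / 16
  steps <- 0L
  last_res <- NA_real_

  while (s_done < 1 - 1e-12) {
    s_try <- min(s_done + ds, 1)
    res <- newton_solve(u, pressure * s_try, pre, phase, free,
                        max_newton, tol, follower)
    total_iter <- total_iter + res$iterations
    last_res <- res$residual
    if (res$converged) {
      u <- res$u
      s_done <- s_try
      steps <- steps + 1L
      if (res$iterations <= 6) ds <- min(ds * 2, 1 / load_steps)
    } else {
      ds <- ds / 2
      if (ds < ds_min) {
        stop(sprintf(
          "FEM solve did not converge (load fraction %.3f, residual %.3e)",
          s_done, res$residual))
      }
    }
  }
  list(u = matrix(u, ncol = 2, byrow = TRUE),
       converged = TRUE, iterations = total_iter,
       residual = last_res, steps = steps)
}

# geometry/fibre precomputation shared by all solves on one mesh
fem_precompute <- function(mesh, params) {
  tri <- mesh$elements
  nd <- mesh$nodes
  x1 <- nd[tri[, 1], ]; x2 <- nd[tri[, 2], ]; x3 <- nd[tri[, 3], ]
  # reference edge matrix M = [X2-X1 | X3-X1]; store inv(M) row-wise
  a <- x2[, 1] - x1[, 1]; b <- x3[, 1] - x1[, 1]
  c_ <- x2[, 2] - x1[, 2]; d <- x3[, 2] - x1[, 2]
  detM <- a * d - b * c_
  if (any(detM <= 0)) stop("element with non-positive area")
  Mi11 <- d / detM;  Mi12 <- -b / detM
  Mi21 <- -c_ / detM; Mi22 <- a / detM
  area <- detM / 2

  fib <- element_fibers(mesh, params$fiber)

  # global dof indices per element-local dof (x1,y1,x2,y2,x3,y3)
  dofs <- cbind(2L * tri[, 1] - 1L, 2L * tri[, 1],
                2L * tri[, 2] - 1L, 2L * tri[, 2],
                2L * tri[, 3] - 1L, 2L * tri[, 3])

  surf <- mesh$surface_faces
  sa <- surf$from
  sb <- surf$to
  sdofs <- cbind(2L * sa - 1L, 2L * sa, 2L * sb - 1L, 2L * sb)

  list(mesh = mesh, params = params, tri = tri,
       Mi11 = Mi11, Mi12 = Mi12, Mi21 = Mi21, Mi22 = Mi22,
       area = area, Nx = fib[, 1], Ny = fib[, 2],
       dofs = dofs, sdofs = sdofs, ndof = 2L * nrow(nd),
       lchar = sqrt(mean(area)))
}

# per-element fibre unit vectors
element_fibers <- function(mesh, fiber) {
  m <- nrow(mesh$elements)
  if (is.matrix(fiber)) {
    stopifnot(nrow(fiber) == m, ncol(fiber) == 2)
    return(fiber / sqrt(rowSums(fiber^2)))
  }
  if (is.numeric(fiber) && length(fiber) == 1) {
    return(cbind(rep(cos(fiber), m), rep(sin(fiber), m)))
  }
  if (identical(fiber, "circumferential")) {
    tri <- mesh$elements
    cx <- (mesh$nodes[tri[, 1], 1] + mesh$nodes[tri[, 2], 1] +
             mesh$nodes[tri[, 3], 1]) / 3
    cy <- (mesh$nodes[tri[, 1], 2] + mesh$nodes[tri[, 2], 2] +
             mesh$nodes[tri[, 3], 2]) / 3
    nb <- mesh$n_boundary
    bp <- mesh$nodes[seq_len(nb), , drop = FALSE]
    nxt <- c(2:nb, 1)
    mx <- (bp[, 1] + bp[nxt, 1]) / 2
    my <- (bp[, 2] + bp[nxt, 2]) / 2
    tx <- bp[nxt, 1] - bp[, 1]
    ty <- bp[nxt, 2] - bp[, 2]
    tl <- sqrt(tx^2 + ty^2)
    near <- vapply(seq_len(m), function(e) {
      which.min((mx - cx[e])^2 + (my - cy[e])^2)
    }, integer(1))
    return(cbind(tx[near] / tl[near], ty[near] / tl[near]))
  }
  stop("unknown fiber specification")
}

# element internal nodal forces as a function of element nodal coordinates.
# xe: m x 6 current coordinates (x1,y1,x2,y2,x3,y3).  Returns m x 6 forces
# or NULL when any element is inverted.
elem_internal_force <- function(xe, pre, phase) {
  d1x <- xe[, 3] - xe[, 1]; d1y <- xe[, 4] - xe[, 2]
  d2x <- xe[, 5] - xe[, 1]; d2y <- xe[, 6] - xe[, 2]
  F11 <- d1x * pre$Mi11 + d2x * pre$Mi21
  F12 <- d1x * pre$Mi12 + d2x * pre$Mi22
  F21 <- d1y * pre$Mi11 + d2y * pre$Mi21
  F22 <- d1y * pre$Mi12 + d2y * pre$Mi22
  J <- F11 * F22 - F12 * F21
  if (any(J <= 0)) return(NULL)
  C11 <- F11^2 + F21^2
  C12 <- F11 * F12 + F21 * F22
  C22 <- F12^2 + F22^2
  S <- pk2_core(C11, C12, C22, pre$Nx, pre$Ny, pre$params, phase)
  P11 <- F11 * S$S11 + F12 * S$S12
  P12 <- F11 * S$S12 + F12 * S$S22
  P21 <- F21 * S$S11 + F22 * S$S12
  P22 <- F21 * S$S12 + F22 * S$S22
  # G = area * P %*% t(Minv)
  G11 <- pre$area * (P11 * pre$Mi11 + P12 * pre$Mi12)
  G12 <- pre$area * (P11 * pre$Mi21 + P12 * pre$Mi22)
  G21 <- pre$area * (P21 * pre$Mi11 + P22 * pre$Mi12)
  G22 <- pre$area * (P21 * pre$Mi21 + P22 * pre$Mi22)
  cbind(-(G11 + G12), -(G21 + G22), G11, G21, G12, G22)
}

# total strain energy at element coordinates xe (m x 6), kPa * px^2
elem_energy <- function(xe, pre, phase) {
  d1x <- xe[, 3] - xe[, 1]; d1y <- xe[, 4] - xe[, 2]
  d2x <- xe[, 5] - xe[, 1]; d2y <- xe[, 6] - xe[, 2]
  F11 <- d1x * pre$Mi11 + d2x * pre$Mi21
  F12 <- d1x * pre$Mi12 + d2x * pre$Mi22
  F21 <- d1y * pre$Mi11 + d2y * pre$Mi21
  F22 <- d1y * pre$Mi12 + d2y * pre$Mi22
  J <- F11 * F22 - F12 * F21
  if (any(J <= 0)) return(NA_real_)
  C11 <- F11^2 + F21^2
  C12 <- F11 * F12 + F21 * F22
  C22 <- F12^2 + F22^2
  I1 <- C11 + C22 + 1
  I4s <- pre$Nx^2 * C11 + 2 * pre$Nx * pre$Ny * C12 + pre$Ny^2 * C22
  I4 <- if (pre$params$i4_convention == "paper_sqrt") sqrt(I4s) else I4s
  W <- strain_energy(I1, I4, pre$params, phase) +
    pre$params$kappa / 2 * (J - 1)^2 +
    pre$params$mu_reg / 2 * (C11 + C22 - 2) - pre$params$mu_reg * log(J)
  sum(pre$area * W)
}

gather_xe <- function(u, pre) {
  coords <- as.vector(t(pre$mesh$nodes)) + u   # interleaved x1,y1,x2,y2,...
  matrix(coords[t(pre$dofs)], ncol = 6, byrow = TRUE)
}

# assemble the global internal force vector; NULL if inverted
internal_force <- function(u, pre, phase) {
  fe <- elem_internal_force(gather_xe(u, pre), pre, phase)
  if (is.null(fe)) return(NULL)
  accumulate_dofs(as.vector(fe), as.vector(pre$dofs), pre$ndof)
}

# follower pressure nodal forces on the SURFACE at current coordinates.
# Positive pressure pushes inward: traction = -p * outward_normal, and for
# an anticlockwise boundary edge a->b the outward normal is (dy, -dx)/L.
external_force <- function(u, pre, p, follower = TRUE) {
  coords <- as.vector(t(pre$mesh$nodes))
  if (follower) coords <- coords + u
  ax <- coords[pre$sdofs[, 1]]; ay <- coords[pre$sdofs[, 2]]
  bx <- coords[pre$sdofs[, 3]]; by <- coords[pre$sdofs[, 4]]
  fx <- -p / 2 * (by - ay)
  fy <- p / 2 * (bx - ax)
  accumulate_dofs(c(fx, fy, fx, fy),
                  c(pre$sdofs[, 1], pre$sdofs[, 2],
                    pre$sdofs[, 3], pre$sdofs[, 4]),
                  pre$ndof)
}

accumulate_dofs <- function(vals, idx, ndof) {
  out <- numeric(ndof)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# tangent stiffness K = d(f_int - f_ext)/du (sparse), by central finite
# differences of the element force plus the analytic follower-load tangent
tangent_stiffness <- function(u, pre, phase, p, follower = TRUE) {
  xe <- gather_xe(u, pre)
  h <- 1e-5 * pre$lchar
  m <- nrow(xe)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (j in 1:6) {
    xp <- xe; xp[, j] <- xp[, j] + h
    xm <- xe; xm[, j] <- xm[, j] - h
    fp <- elem_internal_force(xp, pre, phase)
    fm <- elem_internal_force(xm, pre, phase)
    if (is.null(fp) || is.null(fm)) return(NULL)
    Kj <- (fp - fm) / (2 * h)          # m x 6: dF_i/dx_j per element
    ii <- c(ii, as.vector(pre$dofs))
    jj <- c(jj, rep(pre$dofs[, j], 6))
    vv <- c(vv, as.vector(Kj))
  }
  # follower load tangent: f_ax = -p/2 (by - ay) etc. (see external_force)
  sd <- pre$sdofs
  if (follower)
  for (node_cols in list(c(1, 2), c(3, 4))) {    # force on a, then on b
    fxi <- sd[, node_cols[1]]; fyi <- sd[, node_cols[2]]
    # d f_x / d ay = +p/2 ; d f_x / d by = -p/2  (f_ext enters K with -)
    ii <- c(ii, fxi, fxi, fyi, fyi)
    jj <- c(jj, sd[, 2], sd[, 4], sd[, 1], sd[, 3])
    vv <- c(vv, rep(-p / 2, nrow(sd)), rep(p / 2, nrow(sd)),
            rep(p / 2, nrow(sd)), rep(-p / 2, nrow(sd)))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(pre$ndof, pre$ndof))
}

newton_solve <- function(u, p, pre, phase, free, max_newton, tol, follower = TRUE) {
  iter <- 0L
  repeat {
    iter <- iter + 1L
    fint <- internal_force(u, pre, phase)
    if (is.null(fint)) {
      return(list(converged = FALSE, u = u, iterations = iter,
                  residual = Inf))
    }
    fext <- external_force(u, pre, p, follower)
    R <- fint - fext
    ref <- max(sqrt(sum(fext[free]^2)), 1)
    resid <- sqrt(sum(R[free]^2)) / ref
    if (resid < tol) {
      return(list(converged = TRUE, u = u, iterations = iter,
                  residual = resid))
    }
    if (iter > max_newton) {
      return(list(converged = FALSE, u = u, iterations = iter,
                  residual = resid))
    }
    K <- tangent_stiffness(u, pre, phase, p, follower)
    if (is.null(K)) {
      return(list(converged = FALSE, u = u, iterations = iter,
                  residual = resid))
    }
    du <- tryCatch(
      Matrix::solve(K[free, free, drop = FALSE], -R[free]),
      error = function(e) NULL)
    if (is.null(du) || any(!is.finite(du))) {
      return(list(converged = FALSE, u = u, iterations = iter,
                  residual = resid))
    }
    du <- as.numeric(du)
    # backtracking: shrink the step while it inverts elements or grows
    # the residual
    alpha <- 1
    accepted <- FALSE
    for (ls in 1:8) {
      ut <- u
      ut[free] <- u[free] + alpha * du
      ft <- internal_force(ut, pre, phase)
      if (!is.null(ft)) {
        Rt <- ft - external_force(ut, pre, p, follower)
        rt <- sqrt(sum(Rt[free]^2)) / ref
        if (is.finite(rt) && (rt < resid || ls == 8)) {
          u <- ut
          accepted <- TRUE
          break
        }
      }
      alpha <- alpha / 2
    }
    if (!accepted) {
      return(list(converged = FALSE, u = u, iterations = iter,
                  residual = resid))
    }
  }
}

#' Deformed boundary contour of a solved mesh
#'
#' Adds the nodal displacements to the boundary-chain node coordinates and
#' returns them as a closed contour (basal nodes at their fixed positions
#' close the curve).
#'
#' @param mesh an `lv_mesh` after [assemble_surface()].
#' @param u n x 2 nodal displacement matrix (as returned by
#'   [solve_deformation()]).
#' @param pixel_spacing spacing to stamp on the output contour.
#' @return an `lv_contour`.
#' @export
deformed_boundary_contour <- function(mesh, u, pixel_spacing = 1.0) {
  stopifnot(inherits(mesh, "lv_mesh"))
  if (is.null(mesh$chain)) stop("mesh has no boundary chain; call assemble_surface()")
  pts <- mesh$nodes[mesh$chain, , drop = FALSE] +
    u[mesh$chain, , drop = FALSE]
  contour(pts, pixel_spacing = pixel_spacing, validate = FALSE)
}
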