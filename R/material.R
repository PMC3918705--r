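#' Transversely isotropic myocardium material parameters
#'
#' Parameters of the hyperelastic constitutive model with a passive
#' exponential part
#' \deqn{W_{pass} = c_1 (e^Q - 1),\quad
#'       Q = c_2 (I_1-3)^2 + c_3 (I_1-3)(I_4-1) + c_4 (I_4-1)^2}
#' and an active polynomial part
#' \deqn{W_{act} = c_5 + c_6 (I_1-3)(I_4-1) + c_7 (I_1-3)^2 +
#'       c_8 (I_4-1)^2 + c_9 (I_1-3) + c_{10}(I_4-1),}
#' where \eqn{I_1 = \mathrm{tr}\,C} and \eqn{I_4} measures stretch along the
#' fibre direction N.  During systole the total energy is
#' \eqn{W_{pass} + W_{act}}; during diastole the passive part alone.  A
#' volumetric penalty \eqn{(\kappa/2)(\det F - 1)^2} controls in-plane
#' area change (the model is deliberately compressible in-plane: in this
#' 2D reduction, cavity area change is the deformation being tracked).
#'
#' The numerical defaults are this package's own calibration, NOT values
#' from the experimental literature: they are chosen once so that, under
#' the normal human systolic pressure range of the built-in schedule
#' (10.6--16 kPa), the per-frame contraction over a 16-frame systole
#' accumulates to a physiological area ejection fraction of about 50%
#' (see the methods vignette for the derivation).  For quantitative work
#' supply experimentally determined constants via the config.
#'
#' @param c1,c2,c3,c4 passive constants; `c1` in kPa, the rest
#'   dimensionless.  Requires `c1 > 0` and `4*c2*c4 >= c3^2` (so Q, hence
#'   the passive energy, is non-negative).
#' @param c5,c6,c7,c8,c9,c10 active constants (kPa).
#' @param kappa volumetric penalty modulus in kPa (> 0).
#' @param mu_reg small isotropic neo-Hookean regularisation modulus in kPa
#'   (>= 0).  The exponential I1/I4 energy has zero tangent shear stiffness
#'   at the reference state (in-plane shear changes neither invariant to
#'   first order), which makes the stress-free solid numerically fluid-like
#'   and lets the pressurised boundary wrinkle; a small
#'   \eqn{(\mu/2)(\mathrm{tr}C - 2) - \mu \ln J} term restores a finite
#'   shear modulus without noticeably changing the pressure-area response.
#' @param fiber fibre direction field: `"circumferential"` (per-element
#'   unit tangent of the nearest boundary segment), a single angle in
#'   radians, or an m x 2 matrix of per-element unit vectors.
#' @param i4_convention `"paper_sqrt"` takes \eqn{I_4 = \sqrt{N C N}}
#'   (i.e. the defining relation \eqn{I_4^2 = N_i C_{ij} N_j}); `"standard"` takes
#'   \eqn{I_4 = N C N} as in the original constitutive literature.
#' @return an object of class `lv_material`.
#' @export
material_params <- function(c1 = 2.0, c2 = 16, c3 = -8, c4 = 16,
                            c5 = 0, c6 = 1, c7 = 4, c8 = 1,
                            c9 = 0, c10 = 0,
                            kappa = 100,
                            mu_reg = 20,
                            fiber = "circumferential",
                            i4_convention = c("paper_sqrt", "standard")) {
  i4_convention <- match.arg(i4_convention)
  if (c1 <= 0) stop("c1 must be positive")
  if (4 * c2 * c4 < c3^2) stop("passive Q must be positive semidefinite: 4*c2*c4 >= c3^2")
  if (kappa <= 0) stop("kappa must be positive")
  if (mu_reg < 0) stop("mu_reg must be non-negative")
  structure(list(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, c6 = c6,
                 c7 = c7, c8 = c8, c9 = c9, c10 = c10, kappa = kappa,
                 mu_reg = mu_reg, fiber = fiber,
                 i4_convention = i4_convention),
            class = "lv_material")
}

#' Deformation invariants I1 and I4
#'
#' Plane-strain kinematics: \eqn{C = F^T F} in-plane with \eqn{C_{33} = 1},
#' so \eqn{I_1 = C_{11} + C_{22} + 1}.  Under the `"paper_sqrt"` convention
#' \eqn{I_4 = \sqrt{N_i C_{ij} N_j}} (the fibre stretch); under
#' `"standard"`, \eqn{I_4 = N_i C_{ij} N_j}.
#'
#' @param F 2 x 2 in-plane deformation gradient with `det(F) > 0`.
#' @param N unit fibre direction (length-2).
#' @param convention `"paper_sqrt"` or `"standard"`.
#' @return named numeric `c(I1, I4)`.
#' @export
invariants <- function(F, N, convention = c("paper_sqrt", "standard")) {
  convention <- match.arg(convention)
  F <- matrix(F, 2, 2)
  if (det(F) <= 0) stop("inverted element: det(F) <= 0")
  if (abs(sum(N^2) - 1) > 1e-8) stop("N must be a unit vector")
  C <- t(F) %*% F
  I1 <- C[1, 1] + C[2, 2] + 1
  I4s <- drop(t(N) %*% C %*% N)
  I4 <- if (convention == "paper_sqrt") sqrt(I4s) else I4s
  c(I1 = I1, I4 = I4)
}

#' Strain energy density
#'
#' @param I1,I4 invariants (vectorised).
#' @param params an [material_params()] object.
#' @param phase `"passive"` (diastole: passive energy only) or `"active"`
#'   (systole: passive + active).
#' @return energy density in kPa (per unit reference volume).
#' @export
strain_energy <- function(I1, I4, params,
                          phase = c("passive", "active")) {
  phase <- match.arg(phase)
  q1 <- I1 - 3
  q4 <- I4 - 1
  Q <- params$c2 * q1^2 + params$c3 * q1 * q4 + params$c4 * q4^2
  W <- params$c1 * (exp(Q) - 1)
  if (phase == "active") {
    W <- W + params$c5 + params$c6 * q1 * q4 + params$c7 * q1^2 +
      params$c8 * q4^2 + params$c9 * q1 + params$c10 * q4
  }
  W
}

# vectorised PK2 stress core: inputs are per-element vectors of the
# in-plane C components and fibre vectors; returns S11, S12, S22 (kPa).
# S = 2 dW/dC with W = W_phase(I1, I4) + (kappa/2)(J - 1)^2, J = sqrt(det C).
pk2_core <- function(C11, C12, C22, Nx, Ny, params, phase) {
  q1 <- (C11 + C22 + 1) - 3
  I4s <- Nx * Nx * C11 + 2 * Nx * Ny * C12 + Ny * Ny * C22
  if (params$i4_convention == "paper_sqrt") {
    I4 <- sqrt(I4s)
    dI4_fac <- 1 / (2 * I4)        # dI4/dC = fac * N (x) N
  } else {
    I4 <- I4s
    dI4_fac <- 1
  }
  q4 <- I4 - 1
  eQ <- exp(params$c2 * q1^2 + params$c3 * q1 * q4 + params$c4 * q4^2)
  W1 <- params$c1 * eQ * (2 * params$c2 * q1 + params$c3 * q4)
  W4 <- params$c1 * eQ * (params$c3 * q1 + 2 * params$c4 * q4)
  if (phase == "active") {
    W1 <- W1 + params$c6 * q4 + 2 * params$c7 * q1 + params$c9
    W4 <- W4 + params$c6 * q1 + 2 * params$c8 * q4 + params$c10
  }
  detC <- C11 * C22 - C12^2
  J <- sqrt(detC)
  # d(J)/dC = (J/2) C^{-1}; C^{-1} = [C22, -C12; -C12, C11]/detC
  vol <- params$kappa * (J - 1) * (J / 2) / detC
  # neo-Hookean regularisation: S_reg = mu (I - C^{-1})
  mu <- params$mu_reg
  S11 <- 2 * (W1 + W4 * dI4_fac * Nx * Nx + vol * C22) + mu * (1 - C22 / detC)
  S22 <- 2 * (W1 + W4 * dI4_fac * Ny * Ny + vol * C11) + mu * (1 - C11 / detC)
  S12 <- 2 * (W4 * dI4_fac * Nx * Ny - vol * C12) + mu * (C12 / detC)
  list(S11 = S11, S12 = S12, S22 = S22)
}

#' Second Piola-Kirchhoff stress
#'
#' Analytic \eqn{S = 2\,\partial W_{total}/\partial C} with
#' \eqn{W_{total}} the phase strain energy plus the volumetric penalty
#' \eqn{(\kappa/2)(\det F - 1)^2}, differentiated through the invariants by
#' the chain rule.
#'
#' @inheritParams invariants
#' @param params an [material_params()] object (its `i4_convention` is
#'   used).
#' @param phase `"passive"` or `"active"`.
#' @return symmetric 2 x 2 in-plane stress matrix (kPa).
#' @export
pk2_stress <- function(F, N, params, phase = c("passive", "active")) {
  phase <- match.arg(phase)
  F <- matrix(F, 2, 2)
  if (det(F) <= 0) stop("inverted element: det(F) <= 0")
  C <- t(F) %*% F
  s <- pk2_core(C[1, 1], C[1, 2], C[2, 2], N[1], N[2], params, phase)
  matrix(c(s$S11, s$S12, s$S12, s$S22), 2, 2)
}

#' Cavity pressure schedule over the cardiac cycle
#'
#' During the 16 systolic frames the pressure follows the quadratic
#' time-course \eqn{P(t) = -944.38 t^2 + 245.54 t} kPa with
#' \eqn{t = 0.055 + k \cdot 0.0090625} s for frame k — rising from about
#' 10.65 kPa (~80 mmHg) through a peak of 15.96 kPa (120 mmHg) at
#' t = 0.13 s.  Positive pressure acts inward on the endocardial SURFACE
#' (contraction); during diastole a constant outward (negative) pressure
#' of 5 kPa magnitude is applied (relaxation).
#'
#' @param n_systole number of systolic frames (default 16).
#' @param n_frames total frames in the cycle (default 20).
#' @param diastolic_kpa magnitude of the diastolic outward pressure
#'   (default 5).
#' @param t_offset,t_step time mapping of the systolic frame index
#'   (defaults 0.055 s and 0.0090625 s).
#' @param scale multiplier applied to every frame's pressure (default 1;
#'   0 gives an unloaded schedule).
#' @return an object of class `lv_pressure_schedule`.
#' @export
pressure_schedule <- function(n_systole = 16, n_frames = 20,
                              diastolic_kpa = 5,
                              t_offset = 0.055, t_step = 0.0090625,
                              scale = 1) {
  stopifnot(n_systole >= 1, n_frames >= n_systole, diastolic_kpa >= 0)
  structure(list(n_systole = n_systole, n_frames = n_frames,
                 diastolic_kpa = diastolic_kpa,
                 t_offset = t_offset, t_step = t_step, scale = scale),
            class = "lv_pressure_schedule")
}

# systolic pressure polynomial, kPa as a function of time in seconds
systolic_pressure_curve <- function(t) -944.38 * t^2 + 245.54 * t

#' Signed cavity pressure at a frame
#'
#' @param k 0-based frame index, `0 <= k < n_frames`.  Systolic frames
#'   (`k < n_systole`) return the positive (inward) quadratic pressure;
#'   later frames return the negative (outward) diastolic constant.
#' @param schedule an [pressure_schedule()] object.
#' @return signed pressure in kPa.
#' @export
pressure_at_frame <- function(k, schedule) {
  if (any(k < 0 | k >= schedule$n_frames)) {
    stop("frame index out of range")
  }
  p <- ifelse(k < schedule$n_systole,
              systolic_pressure_curve(schedule$t_offset + k * schedule$t_step),
              -schedule$diastolic_kpa)
  p * schedule$scale
}

#' Convert mmHg to kPa
#' @param mmhg pressure in millimetres of mercury.
#' @return pressure in kPa (1 atm = 760 mmHg = 101.325 kPa).
#' @export
mmhg_to_kpa <- function(mmhg) mmhg * 101.325 / 760
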