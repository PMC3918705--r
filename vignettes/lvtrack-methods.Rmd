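---
title: "lvtrack: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lvtrack: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvtrack)
```

This vignette explains what `lvtrack` computes, the assumptions behind each
stage, why the tunable parameters have the defaults they have, and what the
synthetic phantom does and does not establish.

## The tracking loop

Each frame k of a cardiac cycle (frame 0 = end-diastole, carrying the
user-supplied initial contour) is processed as:

1. **Dynamics prediction.** x̂ₖ = A1 xₖ₋₁ + A2 xₖ₋₂ + (I − A1 − A2) x̄
   applied point-wise to the stacked coordinates.  Defaults A1 = 2,
   A2 = −1 give constant-velocity extrapolation, which makes the mean-shape
   term vanish; x̄ is kept as the running mean of the tracked contours so
   that mean-reverting gains (A1 + A2 < 1) can be configured.
2. **Biomechanical detector.** The previous frame's *tracked* contour is
   remeshed (so element distortion never accumulates across frames), the
   frame's scheduled pressure is applied to the endocardial SURFACE and the
   deformed boundary is extracted from the converged displacement field.
3. **Snake detector.** A Kass active contour evolves from the dynamics
   prediction on the frame's image.
4. **Fusion.** The two contours are merged by iterated normal-intersection
   averaging; the result updates the state.

All contours share one correspondence convention: resampling to a common
point count, uniformly by arc length, anticlockwise, anchored at the point
of maximum y (the apex, under an apex-down convention).  The original
formulation of this framework assumes a one-to-one point correspondence
between contours but never constructs one; the anchored arc-length
resampling is this package's construction and is the basis of the
dynamics, averaging and fusion point maps.

## The biomechanical model

**Kinematics.** Plane strain: the in-plane deformation gradient F gives
C = FᵀF with C₃₃ = 1, so I1 = C₁₁ + C₂₂ + 1 and the fibre invariant is
I4 = √(N·C·N) (the fibre stretch) under the default `paper_sqrt`
convention, which takes the defining relation as I4² = NᵢCᵢⱼNⱼ.  The
conventional I4 = N·C·N of the constitutive literature is available as
`i4_convention = "standard"`.

**Energy.** Diastole uses the passive exponential energy alone; systole
adds the active polynomial (whether the active part replaces or adds to
the passive part is ambiguous in the original formulation; addition is
this package's reading of a constitutive law made of passive and active
parts).  A volumetric penalty (κ/2)(det F − 1)² controls in-plane area
change.  The model is deliberately *compressible* in-plane: in a 2D
single-plane reduction, cavity area change **is** the tracked deformation,
representing out-of-plane blood ejection.

**Regularisation (a finding of this implementation).**  The I1/I4-only
energy has zero tangent shear stiffness at the stress-free reference
state: an in-plane shear increment changes neither I1 nor I4 nor det F to
first order, so the assembled tangent is near-singular in short-wavelength
boundary modes and the pressurised surface wrinkles at spurious limit
points.  A small isotropic neo-Hookean term (μ/2)(tr C − 2) − μ ln(det F)
with μ = `mu_reg` = 20 kPa restores a finite shear modulus.  With it, all
solves over the working pressure range converge in ~40 Newton iterations;
without it, convergence failures appear erratically from ~30% load.  The
term vanishes at the reference and contributes no stress there.

**Material constants.**  No experimentally determined values for c1..c10
were available when this package was written, so the defaults are this
package's own calibration and are *not* literature values.  The
calibration is physiological, fixed once: with the quadratic pressure
schedule re-applied to a freshly remeshed (stress-free) reference
each frame, the per-frame cavity-area reduction at the mean systolic
pressure (≈14.3 kPa) should be ≈4%, so that 16 systolic frames accumulate
to the normal area ejection fraction of ≈50% (0.958¹⁶ ≈ 0.5).  The
defaults c1 = 2 kPa, c2 = 16, c3 = −8, c4 = 16 (passive; they satisfy
4c2c4 ≥ c3², keeping Q ≥ 0), active stiffening c6 = 1, c7 = 4, c8 = 1
with no residual active stress (c5 = c9 = c10 = 0), κ = 100 kPa and
μ = 20 kPa deliver ≈3.8% at 14.27 kPa on the default phantom mesh, and a
BM-only tracked cycle reaches EF ≈ 44%.  For quantitative work supply
experimentally determined constants through the config.

**Fibres.**  The constitutive model leaves the fibre field to the user;
the default
`"circumferential"` assigns each element the unit tangent of its nearest
boundary segment, matching the dominant mid-wall fibre orientation of a
short-axis/long-axis 2D section.

**Pressure.**  Systolic frames k = 0..15: t = 0.055 + 0.0090625 k,
P = −944.38 t² + 245.54 t (kPa), positive = inward.  The curve's vertex is
15.96 kPa (120 mmHg) at t = 0.13 s.  Note a small numerical wrinkle: the
quadratic at k = 0 gives 10.648 kPa, whereas the nominal lower bound of
the normal systolic range is 10.666 kPa (exactly 80 mmHg); the schedule
follows the quadratic, and `mmhg_to_kpa(80)` reproduces 10.666.  The load
is spatially uniform over the SURFACE at each frame: during ejection the
intra-cavity pressure gradients are small against the absolute pressure.
Diastole applies a constant −5 kPa.
Pressure is a follower load (re-oriented along the current surface each
iteration); a dead-load mode exists for diagnostics.

**Solver.**  Total-Lagrangian Newton–Raphson on constant-strain triangles;
analytic internal forces from S = 2∂W/∂C; tangent assembled from central
finite differences of the analytic element force (follower-load tangent
analytic); load stepping (10 increments, halving on divergence, regrowth
after cheap steps) with a backtracking line search that rejects steps
inverting elements; convergence at relative residual < 1e-8.  Basal
restraint: the fraction (default 0.1) of the boundary chain nearest the
minimum-y (valve-plane) end is fully fixed — suppressing rigid-body
motion requires restraining the basal plane, but its extent on an
arbitrary image is a free choice, hence the configurable fraction.

## Meshing

Conforming triangulation of the contour interior: the boundary is
resampled at the target edge length (default perimeter/64; the tracker
uses perimeter/48 for speed), interior nodes sit on a hexagonal lattice
kept ≥ 0.7 h clear of the boundary, the point set is Delaunay-triangulated
(`deldir`), triangles outside the polygon are dropped, and two Laplacian
smoothing sweeps improve quality (minimum angles ≥ 20° on the fixtures).
Boundary faces are identified by the one-element-edge criterion and
numbered anticlockwise (face f joins local nodes f and f mod 3 + 1).  No
installed package provides constrained quality triangulation, so this
layer is hand-built on `deldir`; conformity of every boundary segment is
verified and is an error if violated.

## The snake

Semi-implicit Kass discretisation: internal energy through the inverse of
I + τ(αD₂ + βD₄) (cyclic pentadiagonal), external force −∇E₂ sampled
bilinearly, E₂ = −‖∇I_σ‖² on the σ = 2 px Gaussian-smoothed image.
Defaults α = 0.1, β = 0.05, τ = 0.5, 300 iterations, early stop at
0.01 px maximum displacement, arc-length redistribution every 25
iterations (not part of the classical formulation; needed so the scatter
normals downstream stay well conditioned).  The image-force weight
defaults to 100 because frames are unit-intensity ([0, 1], the `png`
convention): ‖∇I‖² is then O(10⁻²) and its spatial gradient O(10⁻³)/px,
which no classical O(1) weight can move against the 0.01 px stop — on
0..255-scaled data the textbook weight of order 1 plays the same role.

## Fusion

Point-wise averaging plus normal-intersection re-correspondence, iterated
until the maximum point displacement falls below 0.05 px (this package's
quantification of convergence-to-no-change) or 20 iterations.  Normals
come from the local 2×2 scatter matrix over a ±3-point window (the window
half-width is a package choice), normalised by total variance so
a₁₁ + a₂₂ = 1, via the closed-form eigendecomposition; the normal is the
eigenvector of the smaller eigenvalue, oriented outward by the centroid
test (the sign convention is a package choice, needed for consistent ray
casting).  Two numerical details required care: of the closed-form
eigenvector expressions, the variant commonly written for the minor
eigenvector, (a₁₁ − αₘ, a₁₂), is algebraically parallel to the *major*
eigenvector (substituting it into (A − λI)v = 0 shows it satisfies the
major eigenproblem), so the true minor eigenvector (a₁₂, αₘ − a₁₁) is
used and checked against a generic eigensolver; and when a₁₂ = 0 the
closed form is 0/0, so axis-aligned eigenvectors are returned directly.  Lines (not rays) are
intersected with each contour and the intersection nearest the averaged
point is taken; a missing intersection falls back to that contour's
previous correspondence point.  Re-intersection is always with the
original contours.  The same loop with M = 3 builds the evaluation gold
standard.

## Evaluation

APD is one-directional (prediction → reference), 128 arc-length samples,
closest-point (not strict-normal) distance, × pixel spacing; a symmetric
variant is a flag.  EF is area-based — the framework is single-plane, so
no area–length volume model is applied.  Bland–Altman: d = x − y,
bias ± 1.96 sd.

## The phantom: what it emulates, what it does not

The generator rasterises a truncated-ellipse cavity (dark, 0.1) in bright
myocardium (0.85), multiplies by unit-mean gamma speckle with relative
std 0.5 (≈ the 0.52 contrast of fully developed Rayleigh speckle), blurs
at 1.2 px, and optionally replaces an angular sector (measured from the
cavity centroid) by the noise floor — true signal dropout leaves no echo,
and the sector's boundary-gradient magnitude is verified to be < 25% of
the intact wall's.  Frames are not clipped to [0, 1] in memory (clipping
the speckle tail would bias the myocardial mean, which is asserted to be
unit-mean within 2%); clipping happens only at PNG export.  The true
contour contracts radially about the centroid with an apex-weighted
profile (base weight 0.6 → apex 1.0, matching the "more contraction at
apex and lateral wall" behaviour), following a sin² time course to a
minimum radial scale of 0.63 at frame 16 — area EF ≈ 49% — with linear
partial recovery over the 4 diastolic frames.

A green end-to-end test on this phantom establishes that the pipeline
tracks a smoothly contracting chamber through realistic speckle and a
40° dropout and recovers EF within a few points.  It does **not**
establish clinical accuracy: there is no probe geometry, no depth-dependent
point-spread function, no pericardial or valve distractors, and the
motion is exactly the family of deformations the truth model generates.
One consequence is documented honestly in the test suite: with a
well-predicted initialisation and no outside distractors the snake-only
tracker does not leak *globally* at the dropout (its smoothness term
bridges the 40° gap), so the fused contour beats the snake everywhere only
inside the sector — the sector-scoped property is what the suite asserts,
alongside the global bound that fused mean APD stays within 0.2 mm of the
best single detector.

## Numerical choices and degenerate inputs

* Contours must be simple, ≥ 4 points, no repeated consecutive points;
  orientation is normalised at construction.  Zero-area inputs are
  degenerate errors.
* Scatter-matrix eigenvectors: of the two algebraically equivalent
  closed-form expressions per eigenvector, the better-conditioned one is
  used per point (the other cancels catastrophically when a₁₂ → 0 with the
  window axis-aligned).
* FEM finite-difference tangent step: 1e-5 × mean element size; Newton
  tolerance 1e-8 on ‖R‖/max(‖f_ext‖, 1), so the zero-pressure solve
  converges in one iteration with zero displacement.
* Element inversion anywhere in a trial state rejects the Newton step
  (line search, then load-step halving); a solve that cannot complete
  raises an error carrying the last residual, and the tracker falls back
  to the snake contour for that frame with a warning.
* Short sequences cap the systolic frame count at the sequence length.
* The tracker is fully deterministic: the only randomness in the package
  is in the phantom generator, which is seeded.

## Known limitations

* 2D single-plane only; no area–length or Simpson volume model.
* The BM detector's diastolic constant −5 kPa cannot reproduce rapid
  early-diastolic filling; on the phantom the fused contour lags the
  truth in the first diastolic frames.
* The per-frame remeshing makes the model path-dependent by construction
  (each frame starts stress-free): a per-frame solver usage choice, not a
  continuum mechanics statement about the myocardium.
* Open contours and sub-pixel spline representations are out of scope.
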