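# lvtrack

Tracking the left-ventricular (LV) endocardial border through a 2D
echocardiographic image sequence is hard: B-mode images carry speckle,
shadowing and signal dropout, so the true border often has no usable edge,
and purely image-driven segmentation leaks. `lvtrack` implements a tracking
framework that fuses two complementary contour detectors frame by frame:

* a **biomechanical (BM) detector** — the region enclosed by the previous
  frame's contour is meshed with linear triangles and deformed by a
  quasi-static total-Lagrangian finite-element solve of a transversely
  isotropic hyperelastic myocardium model under the frame's cavity
  pressure.  The strain energy is

  W_pass = c1 (e^Q − 1),  Q = c2 (I1−3)² + c3 (I1−3)(I4−1) + c4 (I4−1)²

  with an active systolic polynomial
  W_act = c5 + c6 (I1−3)(I4−1) + c7 (I1−3)² + c8 (I4−1)² + c9 (I1−3) + c10 (I4−1),
  where I1 = tr C and I4 measures stretch along the fibre direction N
  (C = FᵀF).  During the 16 systolic frames the cavity pressure follows
  P(t) = −944.38 t² + 245.54 t kPa with t = 0.055 + 0.0090625 k
  (≈10.65 → 15.96 → 12.5 kPa, i.e. 80–120 mmHg); diastolic frames apply a
  constant outward 5 kPa.  The pressure is a follower load on the
  endocardial SURFACE; basal nodes are fixed.

* a **parametric snake** — the Kass active contour minimising
  ∫ α|c′(s)|² + β|c″(s)|² + E₂(c(s)) ds with image energy
  E₂ = −‖∇I‖², initialised from a second-order shape-dynamics prediction
  x̂ₖ = A1 xₖ₋₁ + A2 xₖ₋₂ + (I − A1 − A2) x̄.

The two contours are merged by **iterated normal-intersection averaging**:
average the corresponded point sets, estimate the outward normal at each
averaged point from the eigenvector of the smaller eigenvalue of a local
2×2 scatter matrix, intersect each normal line with both contours, and
re-average the intersections until the contour stops moving (typically
2–5 iterations).

Also included: the evaluation metrics used in this field (average
perpendicular distance (APD) to a reference, a 3-observer gold standard
built with the same averaging, area curves, area-based ejection fraction,
Bland–Altman agreement) and a seeded echo-phantom generator (bright
myocardium, dark cavity, multiplicative gamma speckle, blur, an angular
signal-dropout sector) with known ground truth, so the whole pipeline is
testable without any clinical data.

## Worked example

Track a 20-frame dropout phantom and compare against its ground truth:

```r
library(lvtrack)

ph  <- make_phantom_sequence(phantom_config(dropout_center_deg = 180,
                                            dropout_width_deg = 40,
                                            seed = 42))
res <- track_sequence(ph$frames, ph$contours[[1]],
                      lv_config(pixel_spacing = 0.5))
res
#> lv_track_result: 20 frames, ED area 1439.1 mm^2, ES area 719.3 mm^2, EF 50.0%

ev <- evaluate_tracking(res, ph$contours)
ev$summary
#>    method mean_apd_mm sd_apd_mm
#> 1 tracked       0.405    0.3002
#> 2      bm       0.657    0.6520
#> 3   snake       0.248    0.0368
```

The phantom's true area EF is 49.4%; the tracker recovers 50.0%, with the
area minimum at end-systole (frame 16).  The summary lists the mean APD of
the fused (tracked) contour and of the two detector contours produced
inside the same run; the fused contour smooths the BM error and, inside
the dropout sector where the snake has no edge to hold it, stays closer to
the truth than the snake.

A thin command-line interface wraps the same functions:

```sh
inst/cli/lvtrack simulate --seed 3 --out phantom/
inst/cli/lvtrack track --frames phantom/ --init init.csv --config cfg.yaml --out out/
inst/cli/lvtrack eval --pred out/ --gold gold/ --spacing 0.5 --out report.json
```

## Acceptance script

`scripts/acceptance.R` regenerates its inputs and recomputes the package's
headline quantity from scratch — it builds 50 seeded pairs of radially
perturbed 128-point ellipses, runs the iterated normal-intersection
averaging on each pair and reports the median iteration count:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

`R/` contour geometry and scatter-matrix normals, meshing, the
constitutive model and FEM solver, snake, fusion, tracking orchestration,
evaluation metrics and the phantom generator; `tests/testthat/` the unit,
property and acceptance suites; `vignettes/lvtrack-methods.Rmd` the
methods notes (model assumptions, parameter choices, numerical decisions,
limitations).
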