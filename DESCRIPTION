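Package: lvtrack
Title: Left Ventricular Endocardium Tracking by Fusion of Biomechanical
    and Active Contour Detectors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tracks the left-ventricular endocardial border through a 2D
    echocardiographic image sequence by fusing two complementary contour
    detectors: a biomechanical detector that deforms the previous frame's
    contour with a transversely isotropic hyperelastic finite-element model
    of the myocardium under a time-varying cavity pressure, and a Kass
    parametric active contour (snake) driven by image gradients.  The two
    contours are merged by an iterated normal-intersection averaging
    procedure.  Includes the evaluation metrics used in this field (average
    perpendicular distance against a multi-observer gold standard,
    area curves, ejection fraction, Bland-Altman agreement) and a seeded
    generator of echo-like speckle phantoms with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deldir,
    sp,
    Matrix,
    png,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
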