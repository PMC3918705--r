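test_that("contour construction enforces the invariants", {
  expect_error(contour(rbind(c(0, 0), c(1, 0), c(1, 1))), "at least 4")
  expect_error(contour(rbind(c(0, 0), c(0, 0), c(1, 0), c(1, 1), c(0, 1))),
               "repeated consecutive")
  # crossing quadrilateral with non-zero area
  expect_error(contour(rbind(c(0, 0), c(6, 0), c(6, 4), c(3, -2), c(0, 4))),
               "self-intersecting")
  # zero-area bow-tie is caught as degenerate
  expect_error(contour(rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))),
               "degenerate")
  # clockwise input is normalised to anticlockwise
  cw <- contour(rbind(c(0, 1), c(1, 1), c(1, 0), c(0, 0)))
  expect_gt(lvtrack:::signed_area(cw$points), 0)
  # repeated closing point is dropped
  cc <- contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0)))
  expect_equal(nrow(cc$points), 4)
})

test_that("resample_closed divides the perimeter uniformly and anchors at the apex", {
  sq <- contour(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  r8 <- resample_closed(sq, 8)
  pts <- r8$points
  gaps <- sqrt(rowSums((pts[c(2:8, 1), ] - pts)^2))
  expect_equal(gaps, rep(5, 8), tolerance = 1e-12)
  expect_equal(unname(pts[1, 2]), max(pts[, 2]))   # starts at maximum y

  # n = current size on an already-uniform contour: same point set
  circ <- circle_contour(10, 64)
  r <- resample_closed(circ, 64)
  d <- lvtrack:::dist_to_polyline(r$points, circ$points)
  expect_lt(max(d), 1e-9)

  # unit circle downsample stays on radius 1
  uc <- circle_contour(1, 64)
  r16 <- resample_closed(uc, 16)
  expect_true(all(abs(sqrt(rowSums(r16$points^2)) - 1) < 1e-3))

  expect_error(resample_closed(circ, 3), "at least 4")
})

test_that("resample_closed preserves the perimeter for n >= input size", {
  for (cc in list(circle_contour(25, 40), blob_contour(7),
                  ellipse_contour(30, 50, 64))) {
    for (n in c(nrow(cc$points), 2 * nrow(cc$points))) {
      r <- resample_closed(cc, n)
      expect_lt(abs(perimeter(r) - perimeter(cc)) / perimeter(cc), 0.01)
    }
  }
})

test_that("polygon_area matches closed forms and is rigid-invariant", {
  expect_equal(polygon_area(unit_square()), 1.0)
  # regular 64-gon inscribed in radius 10
  expect_equal(polygon_area(circle_contour(10, 64)),
               0.5 * 64 * 100 * sin(2 * pi / 64), tolerance = 1e-12)
  b <- blob_contour(3)
  a0 <- polygon_area(b)
  for (i in 1:5) {
    th <- i * 0.7
    moved <- contour(b$points %*% rot2(th) + rep(c(13.7, -4.2), each = nrow(b$points)))
    expect_lt(abs(polygon_area(moved) - a0) / a0, 1e-9)
  }
  # mm scaling
  sq <- contour(unit_square()$points, pixel_spacing = 0.5)
  expect_equal(polygon_area(sq, units = "mm"), 0.25)
})

test_that("contour CSV and JSON round-trip", {
  b <- blob_contour(9)
  b$pixel_spacing <- 0.7
  csv <- tempfile(fileext = ".csv")
  json <- tempfile(fileext = ".json")
  write_contour_csv(b, csv)
  back <- read_contour_csv(csv, pixel_spacing = 0.7)
  expect_equal(back$points, b$points, tolerance = 1e-12)
  write_contour_json(b, json)
  back2 <- read_contour_json(json)
  expect_equal(back2$points, b$points, tolerance = 1e-12)
  expect_equal(back2$pixel_spacing, 0.7)
  unlink(c(csv, json))
})
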