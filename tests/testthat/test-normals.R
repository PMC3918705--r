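test_that("scatter matrix is normalised and matches the eigen oracle", {
  set.seed(42)
  for (i in 1:50) {
    pts <- matrix(rnorm(14, sd = runif(1, 0.5, 5)), 7, 2)
    sm <- scatter_matrix(pts)
    expect_equal(sm$a11 + sm$a22, 1, tolerance = 1e-12)
    expect_equal(sm$alpha_M + sm$alpha_m, 1, tolerance = 1e-12)
    A <- matrix(c(sm$a11, sm$a12, sm$a12, sm$a22), 2, 2)
    eo <- eigen(A, symmetric = TRUE)
    expect_lt(abs(sm$alpha_M - eo$values[1]), 1e-10)
    expect_lt(abs(sm$alpha_m - eo$values[2]), 1e-10)
    # eigenvectors parallel to the oracle's (sign-free): |cross| ~ 0
    expect_lt(abs(sm$aM[1] * eo$vectors[2, 1] - sm$aM[2] * eo$vectors[1, 1]),
              1e-10)
    expect_lt(abs(sm$am[1] * eo$vectors[2, 2] - sm$am[2] * eo$vectors[1, 2]),
              1e-10)
    expect_lt(abs(sum(sm$aM * sm$am)), 1e-12)    # orthogonal
  }
  expect_error(scatter_matrix(matrix(1, 5, 2)), "degenerate")
})

test_that("scatter normal of collinear points is perpendicular to the line", {
  pts <- cbind(seq(-3, 3), 0)         # along the x axis
  sm <- scatter_matrix(pts)
  expect_equal(abs(sm$am), c(0, 1), tolerance = 1e-12)
  # rotated line
  pts2 <- pts %*% rot2(0.6)          # row-vector convention: rotate by -0.6
  sm2 <- scatter_matrix(pts2)
  expect_lt(abs(sum(sm2$am * c(cos(0.6), -sin(0.6)))), 1e-10)
})

test_that("local normals on a circle are radial and outward", {
  circ <- circle_contour(20, 64)
  nn <- contour_normals(circ, window = 3)
  radial <- circ$points / 20
  ang <- acos(pmin(1, rowSums(nn * radial))) * 180 / pi
  expect_lt(max(ang), 2)              # within 2 degrees, outward
  # single-point API agrees with the vectorised one
  for (i in c(1, 17, 40)) {
    expect_equal(local_normal(circ, i, window = 3), nn[i, ],
                 tolerance = 1e-12)
  }
})

test_that("local_normal is equivariant under rigid rotation", {
  b <- blob_contour(11)
  th <- 0.83
  br <- contour(b$points %*% rot2(th))
  for (i in c(2, 10, 25)) {
    n1 <- local_normal(b, i, 3)
    n2 <- local_normal(br, i, 3)
    expect_equal(as.numeric(n1 %*% rot2(th)), n2, tolerance = 1e-6)
  }
})

test_that("ray-polyline intersection returns the nearest hit", {
  circ <- circle_contour(10, 64)
  # directions through vertices: exact distance 10
  for (i in c(1, 9, 30)) {
    d <- circ$points[i, ] / 10
    p <- intersect_ray_polyline(c(0, 0), d, circ)
    expect_lt(abs(sqrt(sum(p^2)) - 10), 1e-9)
  }
  # origin on the contour: that point itself (t = 0)
  p0 <- intersect_ray_polyline(circ$points[5, ], c(0.3, 0.95), circ)
  expect_equal(as.numeric(p0), unname(circ$points[5, ]), tolerance = 1e-9)
  # line missing the polygon entirely
  expect_null(intersect_ray_polyline(c(100, 100), c(0, 1), circ))
  expect_error(intersect_ray_polyline(c(0, 0), c(0, 0), circ), "non-zero")
})

test_that("intersections land on contour segments (brute-force check)", {
  set.seed(7)
  poly <- blob_contour(13)
  for (i in 1:100) {
    th <- runif(1, 0, 2 * pi)
    origin <- polygon_centroid(poly) + runif(2, -3, 3)
    p <- intersect_ray_polyline(origin, c(cos(th), sin(th)), poly)
    expect_false(is.null(p))
    resid <- min(lvtrack:::dist_to_polyline(matrix(p, 1), poly$points))
    expect_lt(resid, 1e-9)
  }
})
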