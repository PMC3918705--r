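test_that("phantom generation is fully determined by the seed", {
  cfg <- phantom_config(n_frames = 4, seed = 7)
  p1 <- make_phantom_sequence(cfg)
  p2 <- make_phantom_sequence(cfg)
  expect_identical(p1$frames, p2$frames)
  expect_identical(p1$contours[[2]]$points, p2$contours[[2]]$points)
  p3 <- make_phantom_sequence(phantom_config(n_frames = 4, seed = 8))
  expect_false(identical(p1$frames[[1]], p3$frames[[1]]))
})

test_that("a noise-free phantom is two-level with the boundary on the truth", {
  cfg <- phantom_config(n_frames = 2, speckle_scale = 0, blur_sigma = 0)
  ph <- make_phantom_sequence(cfg)
  img <- ph$frames[[1]]
  expect_setequal(unique(as.vector(img)),
                  c(cfg$myo_intensity, cfg$cavity_intensity))
  # stepping 1 px inward/outward along the normal crosses the level set
  tr <- resample_closed(ph$contours[[1]], 64)
  nn <- contour_normals(tr, 3)
  inner <- tr$points - 1.0 * nn
  outer <- tr$points + 1.0 * nn
  gi <- lvtrack:::bilinear_sample(img, inner[, 1], inner[, 2])
  go <- lvtrack:::bilinear_sample(img, outer[, 1], outer[, 2])
  mid <- (cfg$myo_intensity + cfg$cavity_intensity) / 2
  expect_gt(mean(gi < mid), 0.95)
  expect_gt(mean(go > mid), 0.95)
})

test_that("truth summary matches its construction", {
  ph <- make_phantom_sequence(phantom_config())
  expect_equal(ph$ef, 100 * (1 - min(ph$areas_mm2) / ph$areas_mm2[1]),
               tolerance = 1e-12)
  expect_equal(which.min(ph$areas_mm2) - 1, 16)   # end-systole
  expect_equal(length(ph$frames), 20)
})

test_that("speckle is unit-mean over the myocardium", {
  cfg <- phantom_config(blur_sigma = 0)
  ph <- make_phantom_sequence(cfg)
  img <- ph$frames[[1]]
  S <- cfg$image_size
  xs <- rep(seq_len(S), each = S); ys <- rep(seq_len(S), times = S)
  inside <- sp::point.in.polygon(xs, ys, ph$contours[[1]]$points[, 1],
                                 ph$contours[[1]]$points[, 2]) > 0
  myo <- img[cbind(ys[!inside], xs[!inside])]
  expect_lt(abs(mean(myo) - cfg$myo_intensity) / cfg$myo_intensity, 0.02)
})

test_that("the dropout sector kills the boundary gradient", {
  cfg <- phantom_config(dropout_center_deg = 180, dropout_width_deg = 40)
  ph <- make_phantom_sequence(cfg)
  img <- ph$frames[[1]]
  g <- lvtrack:::image_gradient(lvtrack:::gaussian_blur(img, 2))
  gm <- sqrt(g$gx^2 + g$gy^2)
  tr <- resample_closed(ph$contours[[1]], 256)
  ctr <- polygon_centroid(tr)
  ang <- atan2(tr$points[, 2] - ctr[2], tr$points[, 1] - ctr[1]) * 180 / pi
  dd <- abs(((ang - 180 + 180) %% 360) - 180)
  on_edge <- lvtrack:::bilinear_sample(gm, tr$points[, 1], tr$points[, 2])
  sector <- dd <= 15
  expect_lt(mean(on_edge[sector]), 0.25 * mean(on_edge[!sector]))
})

test_that("noisy contour sets are seeded, unbiased and simple", {
  base <- resample_closed(ellipse_contour(40, 60), 128)
  c0 <- make_noisy_contour_set(base, 3, 0, seed = 1)
  for (cc in c0) expect_equal(cc$points, base$points, tolerance = 1e-12)
  a <- make_noisy_contour_set(base, 2, 2, seed = 5)
  b <- make_noisy_contour_set(base, 2, 2, seed = 5)
  expect_identical(a[[1]]$points, b[[1]]$points)
  # CLT: the point-wise mean of many copies approaches the base
  m <- 200
  cs <- make_noisy_contour_set(base, m, 2, seed = 2)
  mu <- Reduce(`+`, lapply(cs, `[[`, "points")) / m
  # the 5-point moving average leaves ~sigma/sqrt(5) per-point noise
  expect_lt(max(abs(mu - base$points)), 3 * 2 / sqrt(m) + 0.1)
  for (cc in cs[1:20]) {
    expect_true(lvtrack:::is_simple_polygon(cc$points))
  }
})

test_that("phantom sequences round-trip through disk", {
  dir <- tempfile()
  ph <- make_phantom_sequence(phantom_config(n_frames = 3))
  write_phantom(ph, dir)
  frames <- read_frames(dir)
  expect_equal(length(frames), 3)
  expect_equal(frames[[1]], pmax(pmin(ph$frames[[1]], 1), 0),
               tolerance = 1 / 255)
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  expect_equal(truth$ef, ph$ef, tolerance = 1e-9)
  cc <- read_contour_csv(file.path(dir, "truth_000.csv"), pixel_spacing = 0.5)
  expect_equal(cc$points, ph$contours[[1]]$points, tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
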