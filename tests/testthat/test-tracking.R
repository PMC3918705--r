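test_that("the second-order dynamics prediction follows its closed forms", {
  b <- resample_closed(blob_contour(1, r = 30), 64)
  b2 <- contour(b$points * 0.95, validate = FALSE)
  xbar <- contour(b$points * 1.1, validate = FALSE)
  st <- list(x_prev = b, x_prev2 = b2, mean_shape = xbar, A1 = 2, A2 = -1)
  expect_equal(predict_contour(st)$points, 2 * b$points - b2$points,
               tolerance = 1e-12)
  st$A1 <- 1; st$A2 <- 0
  expect_equal(predict_contour(st)$points, b$points, tolerance = 1e-12)
  st$A1 <- 0; st$A2 <- 0
  expect_equal(predict_contour(st)$points, xbar$points, tolerance = 1e-12)
  st$x_prev2 <- resample_closed(b, 32)
  expect_error(predict_contour(st), "mismatched")
})

test_that("config handles overrides and YAML round-trip", {
  cfg <- lv_config(snake = list(alpha = 0.3), pixel_spacing = 0.4)
  expect_equal(cfg$snake$alpha, 0.3)
  expect_equal(cfg$mesh$n_boundary, 48)
  expect_error(lv_config(bogus = 1), "unknown config")
  f <- tempfile(fileext = ".yaml")
  writeLines(c("snake:", "  alpha: 0.25", "pixel_spacing: 0.7",
               "tracking:", "  method: snake"), f)
  cfg2 <- read_config(f)
  expect_equal(cfg2$snake$alpha, 0.25)
  expect_equal(cfg2$pixel_spacing, 0.7)
  expect_equal(cfg2$tracking$method, "snake")
  unlink(f)
})

test_that("a static unloaded phantom is tracked without drift", {
  cfg_ph <- phantom_config(n_frames = 2, contraction_min = 1)
  ph <- make_phantom_sequence(cfg_ph)
  frames <- rep(ph$frames[1], 6)          # all frames identical
  cfg <- lv_config(pressure = list(scale = 0),
                   tracking = list(n_points = 96),
                   pixel_spacing = 0.5)
  res <- track_sequence(frames, ph$contours[[1]], cfg)
  for (r in res$results) {
    expect_lt(apd(r$contour, ph$contours[[1]]) / 0.5, 1)   # within 1 px
  }
  expect_lt(res$ef, 5)
})

test_that("tracking is deterministic", {
  ph <- make_phantom_sequence(phantom_config(n_frames = 4))
  cfg <- lv_config(tracking = list(n_points = 96), pixel_spacing = 0.5)
  r1 <- track_sequence(ph$frames[1:4], ph$contours[[1]], cfg)
  r2 <- track_sequence(ph$frames[1:4], ph$contours[[1]], cfg)
  expect_identical(r1$areas_mm2, r2$areas_mm2)
  expect_identical(r1$results[[3]]$contour$points,
                   r2$results[[3]]$contour$points)
})

test_that("fusion shields the tracker inside a signal-dropout sector", {
  # inside the 40-degree dropout sector the snake has no edge to hold it;
  # the biomechanical prior keeps the fused contour closer to the truth
  cfg_ph <- phantom_config(dropout_center_deg = 180, dropout_width_deg = 40)
  ph <- make_phantom_sequence(cfg_ph)
  frames <- ph$frames[1:11]               # systolic half of the cycle
  sector_apd <- function(cc, truth) {
    s <- resample_closed(cc, 128)$points
    ctr <- polygon_centroid(truth)
    ang <- atan2(s[, 2] - ctr[2], s[, 1] - ctr[1]) * 180 / pi
    sel <- abs(((ang - 180 + 180) %% 360) - 180) <= 20
    mean(lvtrack:::dist_to_polyline(s[sel, , drop = FALSE],
                                    truth$points)) * 0.5
  }
  run <- function(method) {
    cfg <- lv_config(tracking = list(method = method), pixel_spacing = 0.5)
    suppressWarnings(track_sequence(frames, ph$contours[[1]], cfg))
  }
  rf <- run("fused")
  rs <- run("snake")
  sf <- vapply(seq_along(rf$results), function(i)
    sector_apd(rf$results[[i]]$contour, ph$contours[[i + 1]]), numeric(1))
  ss <- vapply(seq_along(rs$results), function(i)
    sector_apd(rs$results[[i]]$contour, ph$contours[[i + 1]]), numeric(1))
  expect_lt(mean(sf), mean(ss))
})
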