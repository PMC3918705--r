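#' Configuration of the echo-like phantom generator
#'
#' The phantom emulates the appearance of a single-plane B-mode
#' echocardiographic view of a normal left ventricle: a dark blood pool
#' inside bright myocardium, multiplicative speckle texture, point-spread
#' blur and, optionally, an angular signal-dropout sector in which the
#' endocardial edge disappears (the scenario in which an image-driven snake
#' leaks).  The cavity is a truncated ellipse, apex down (maximum y), with
#' the basal (valve) end at the top.  Over a 20-frame cycle with 16
#' systolic frames the true contour contracts radially about its centroid
#' with an apex-weighted profile — more contraction at the apex and lateral
#' wall, less at the base — reaching minimum area at end-systole
#' (frame 16) and partially recovering afterwards.  The default minimum
#' radial scale of 0.63 yields an area ejection fraction of roughly 50%,
#' a normal value for a 2D area-based measure.
#'
#' @param image_size image side in pixels (square frames), default 160.
#' @param center cavity centre (x, y) in pixels.
#' @param semi_axes (a, b): x and y semi-axes of the ellipse in pixels.
#' @param basal_cut fraction of `b` above the centre at which the ellipse
#'   is truncated by the basal chord (default 0.75).
#' @param n_frames frames in the cycle (default 20).
#' @param n_systole systolic frames (default 16).
#' @param contraction_min minimum radial scale at end-systole, in
#'   `(0.5, 1]` (default 0.63).
#' @param apex_weight_base relative contraction weight at the base
#'   (apex = 1), default 0.6.
#' @param myo_intensity,cavity_intensity mean intensities in `[0, 1]`
#'   (defaults 0.85 and 0.1).
#' @param speckle_scale relative std of the unit-mean multiplicative gamma
#'   speckle (default 0.5, near the 0.52 contrast of fully developed
#'   Rayleigh speckle in B-mode imaging; 0 disables).
#' @param blur_sigma Gaussian blur in pixels (default 1.2; 0 disables).
#' @param dropout_center_deg,dropout_width_deg,dropout_attenuation angular
#'   signal-dropout sector measured from the cavity centroid (width 0
#'   disables; the default attenuation 1 replaces the sector by the noise
#'   floor, as true dropout leaves no echo).
#' @param noise_floor intensity floor of the dropout sector (default 0.05).
#' @param pixel_spacing mm per pixel (default 0.5).
#' @param seed RNG seed making the sequence fully reproducible.
#' @return an object of class `lv_phantom_config`.
#' @export
phantom_config <- function(image_size = 160,
                           center = c(80, 86),
                           semi_axes = c(38, 52),
                           basal_cut = 0.75,
                           n_frames = 20,
                           n_systole = 16,
                           contraction_min = 0.63,
                           apex_weight_base = 0.6,
                           myo_intensity = 0.85,
                           cavity_intensity = 0.1,
                           speckle_scale = 0.5,
                           blur_sigma = 1.2,
                           dropout_center_deg = 0,
                           dropout_width_deg = 0,
                           dropout_attenuation = 1.0,
                           noise_floor = 0.05,
                           pixel_spacing = 0.5,
                           seed = 1) {
  if (contraction_min <= 0.5 || contraction_min > 1) {
    stop("contraction_min must lie in (0.5, 1]")
  }
  if (n_frames < 2) stop("need at least 2 frames")
  if (any(c(myo_intensity, cavity_intensity) < 0 |
          c(myo_intensity, cavity_intensity) > 1)) {
    stop("intensities must lie in [0, 1]")
  }
  structure(as.list(environment()), class = "lv_phantom_config")
}

# truncated-ellipse base contour (apex at maximum y, basal chord on top)
phantom_base_contour <- function(config, n = 128) {
  a <- config$semi_axes[1]; b <- config$semi_axes[2]
  cx <- config$center[1]; cy <- config$center[2]
  thc <- acos(-config$basal_cut)                # arc where y >= y_cut
  th <- seq(-thc, thc, length.out = 181)
  pts <- cbind(cx + a * sin(th), cy + b * cos(th))
  resample_closed(contour(pts, pixel_spacing = config$pixel_spacing),
                  n)
}

# per-frame radial scale profile: 1 at frame 0, minimum at end-systole,
# linear partial recovery through diastole
phantom_scale_profile <- function(config) {
  k <- seq_len(config$n_frames) - 1
  rho <- numeric(config$n_frames)
  sys <- k <= config$n_systole
  rho[sys] <- 1 - (1 - config$contraction_min) *
    sin(pi / 2 * k[sys] / config$n_systole)^2
  rec <- (k[!sys] - config$n_systole) /
    max(1, config$n_frames - config$n_systole)
  rho[!sys] <- config$contraction_min +
    (1 - config$contraction_min) * rec
  rho
}

# deform the base contour by an apex-weighted radial scale about the
# centroid: weight apex_weight_base at the basal (min y) end, 1 at the apex
phantom_true_contour <- function(base, rho, config) {
  pts <- base$points
  ctr <- polygon_centroid(base)
  yr <- range(pts[, 2])
  w <- config$apex_weight_base +
    (1 - config$apex_weight_base) * (pts[, 2] - yr[1]) / diff(yr)
  s <- 1 - (1 - rho) * w
  out <- cbind(ctr[1] + s * (pts[, 1] - ctr[1]),
               ctr[2] + s * (pts[, 2] - ctr[2]))
  contour(out, pixel_spacing = config$pixel_spacing, validate = FALSE)
}

# rasterise one frame: bright myocardium everywhere, dark cavity inside
# the contour, then speckle, blur and the dropout sector
phantom_render <- function(true_contour, config) {
  S <- config$image_size
  xs <- rep(seq_len(S), each = S)     # column-major grid: y fast
  ys <- rep(seq_len(S), times = S)
  inside <- sp::point.in.polygon(xs, ys, true_contour$points[, 1],
                                 true_contour$points[, 2]) > 0
  img <- matrix(config$myo_intensity, S, S)
  img[cbind(ys[inside], xs[inside])] <- config$cavity_intensity
  if (config$speckle_scale > 0) {
    shape <- 1 / config$speckle_scale^2
    img <- img * matrix(stats::rgamma(S * S, shape = shape,
                                      rate = shape), S, S)
  }
  if (config$blur_sigma > 0) img <- gaussian_blur(img, config$blur_sigma)
  if (config$dropout_width_deg > 0) {
    ctr <- polygon_centroid(true_contour)
    ang <- atan2(ys - ctr[2], xs - ctr[1]) * 180 / pi
    dd <- abs(((ang - config$dropout_center_deg + 180) %% 360) - 180)
    sect <- dd <= config$dropout_width_deg / 2
    att <- config$dropout_attenuation
    sel <- cbind(ys[sect], xs[sect])
    img[sel] <- config$noise_floor + (1 - att) *
      (img[sel] - config$noise_floor)
  }
  # no clipping here: clipping the speckle tail would bias the myocardial
  # mean; values are clipped to [0, 1] only when written as PNG
  img
}

#' Generate an echo-like phantom sequence with known ground truth
#'
#' @param config an [phantom_config()] object.
#' @return list of class `lv_phantom`: `frames` (list of image matrices),
#'   `contours` (list of true `lv_contour`s), `areas_mm2` (true area
#'   curve), `ef` (true area ejection fraction, percent, equal to
#'   `100 * (1 - min(area)/area[1])` by construction), `config`.
#' @export
make_phantom_sequence <- function(config = phantom_config()) {
  stopifnot(inherits(config, "lv_phantom_config"))
  set.seed(config$seed)
  base <- phantom_base_contour(config)
  if (any(base$points < 1) || any(base$points > config$image_size)) {
    stop("phantom contour exits image bounds")
  }
  rho <- phantom_scale_profile(config)
  contours <- lapply(rho, function(r) phantom_true_contour(base, r, config))
  frames <- lapply(contours, phantom_render, config = config)
  areas <- vapply(contours, polygon_area, numeric(1), units = "mm")
  structure(list(frames = frames, contours = contours,
                 areas_mm2 = areas,
                 ef = ejection_fraction(areas[1], min(areas)),
                 config = config),
            class = "lv_phantom")
}

#' Radially perturbed copies of a contour
#'
#' Fixture generator for the fusion and gold-standard tests: `m` copies of
#' `base` with independent per-point radial Gaussian noise about the
#' centroid, smoothed with a cyclic 5-point moving average so the copies
#' stay simple.
#'
#' @param base an `lv_contour`.
#' @param m number of copies (>= 1).
#' @param sigma_px radial noise standard deviation in pixels.
#' @param seed RNG seed.
#' @return list of `m` `lv_contour`s.
#' @export
make_noisy_contour_set <- function(base, m, sigma_px, seed = 1) {
  stopifnot(inherits(base, "lv_contour"), m >= 1)
  set.seed(seed)
  ctr <- polygon_centroid(base)
  pts <- base$points
  n <- nrow(pts)
  rad <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  ux <- (pts[, 1] - ctr[1]) / rad
  uy <- (pts[, 2] - ctr[2]) / rad
  make_one <- function(p) {
    if (sigma_px == 0) return(p)
    eps <- stats::rnorm(n, 0, sigma_px)
    out <- cbind(p[, 1] + eps * ux, p[, 2] + eps * uy)
    # cyclic 5-point moving average keeps the copy simple
    sm <- out
    for (o in c(-2, -1, 1, 2)) {
      sm <- sm + out[((seq_len(n) - 1 + o) %% n) + 1, , drop = FALSE]
    }
    sm / 5
  }
  lapply(seq_len(m), function(i) {
    out <- make_one(pts)
    if (sigma_px > 0 && !is_simple_polygon(out)) {
      out <- make_one(resample_closed(base, n)$points)   # one retry
      if (!is_simple_polygon(out)) {
        stop("perturbation produced a self-intersecting contour")
      }
    }
    contour(out, pixel_spacing = base$pixel_spacing, validate = FALSE)
  })
}

#' Write a phantom sequence to disk
#'
#' Frames as zero-padded PNGs, true contours as CSVs and the truth summary
#' (areas, EF, pixel spacing) as JSON.
#'
#' @param phantom an `lv_phantom` from [make_phantom_sequence()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nf <- length(phantom$frames)
  for (i in seq_len(nf)) {
    write_frame(phantom$frames[[i]],
                file.path(dir, sprintf("frame_%03d.png", i - 1)))
    write_contour_csv(phantom$contours[[i]],
                      file.path(dir, sprintf("truth_%03d.csv", i - 1)))
  }
  jsonlite::write_json(
    list(areas_mm2 = phantom$areas_mm2, ef = phantom$ef,
         pixel_spacing_mm = phantom$config$pixel_spacing,
         n_frames = nf),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
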