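#' Tracker configuration
#'
#' Nested configuration for [track_sequence()], overridable from YAML via
#' [read_config()].  Sections: `material` ([material_params()] arguments),
#' `pressure` ([pressure_schedule()] arguments), `snake`
#' ([snake_params()] arguments), `mesh` (`n_boundary` boundary nodes per
#' frame mesh, `basal_fraction`), `fusion` (`tol`, `max_iter`, `window`),
#' `tracking` (`n_points` contour control points, scalar dynamics gains
#' `A1`, `A2`, `method` one of `"fused"`, `"bm"`, `"snake"`), and
#' `pixel_spacing` (mm per pixel).
#'
#' @param ... named overrides, e.g. `snake = list(alpha = 0.2)`; unknown
#'   keys are an error.
#' @return a nested list of class `lv_config`.
#' @export
lv_config <- function(...) {
  cfg <- list(
    material = list(),
    pressure = list(),
    snake = list(),
    mesh = list(n_boundary = 48, basal_fraction = 0.1),
    fusion = list(tol = 0.05, max_iter = 20, window = 3),
    tracking = list(n_points = 128, A1 = 2, A2 = -1, method = "fused"),
    solver = list(tol = 1e-8, max_newton = 50, load_steps = 10),
    pixel_spacing = 1.0
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config section: ", nm)
    if (is.list(cfg[[nm]])) {
      for (k in names(over[[nm]])) cfg[[nm]][[k]] <- over[[nm]][[k]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = "lv_config")
}

#' Read a YAML tracker config
#'
#' Keys mirror [lv_config()]; missing keys keep their defaults.
#'
#' @param path YAML file.
#' @return an `lv_config`.
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(lv_config, obj)
}

config_schedule <- function(config, n_frames) {
  args <- config$pressure
  args$n_frames <- max(n_frames, args$n_frames %||% n_frames)
  # short sequences: systole cannot outlast the recording
  args$n_systole <- min(args$n_systole %||% 16, args$n_frames)
  do.call(pressure_schedule, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Second-order dynamics prediction of the next contour
#'
#' \deqn{\hat{x}_k = A_1 x_{k-1} + A_2 x_{k-2} + (I - A_2 - A_1)\bar{x}}
#' applied coordinate-wise to the stacked point vectors.  The defaults
#' `A1 = 2`, `A2 = -1` give constant-velocity extrapolation (the mean-shape
#' term vanishes).
#'
#' @param state tracking state: list with `x_prev`, `x_prev2`
#'   (`lv_contour`s at k-1, k-2), `mean_shape` (`lv_contour`), and scalar
#'   gains `A1`, `A2`.
#' @return the predicted `lv_contour`.
#' @export
predict_contour <- function(state) {
  p1 <- state$x_prev$points
  p2 <- state$x_prev2$points
  pm <- state$mean_shape$points
  if (!all(dim(p1) == dim(p2)) || !all(dim(p1) == dim(pm))) {
    stop("state contours have mismatched shapes")
  }
  pts <- state$A1 * p1 + state$A2 * p2 + (1 - state$A1 - state$A2) * pm
  contour(pts, pixel_spacing = state$x_prev$pixel_spacing,
          validate = FALSE)
}

#' Track the LV endocardium through an image sequence
#'
#' Per frame k (frame 0 carries the initial contour): predict the contour
#' with the second-order dynamics; rebuild the undeformed FE mesh from the
#' previous frame's output contour; solve the biomechanical model at the
#' frame's scheduled pressure and extract the deformed boundary (the BM
#' contour); evolve the snake from the dynamics prediction on the frame's
#' image; fuse the BM and snake contours by normal-intersection averaging;
#' update the state.  A failed BM solve falls back to the snake contour for
#' that frame (with a warning).  After the last frame the area curve and
#' the area ejection fraction are computed.
#'
#' @param frames list of image matrices, or a directory of PNG frames.
#' @param init initial end-diastolic `lv_contour` on frame 0.
#' @param config an [lv_config()].
#' @return object of class `lv_track_result`: `results` (per-frame lists
#'   with `bm_contour`, `snake_contour`, `fused_contour`, `contour` (the
#'   tracked output), `pressure_kpa`, `area_mm2`, solver and fusion
#'   diagnostics), `areas_mm2` (length n_frames, frame 0 = init),
#'   `ef` (percent), `config`.
#' @export
track_sequence <- function(frames, init, config = lv_config()) {
  if (is.character(frames)) frames <- read_frames(frames)
  nf <- length(frames)
  if (nf < 2) stop("need at least 2 frames")
  stopifnot(inherits(init, "lv_contour"))
  spacing <- config$pixel_spacing
  n_pts <- config$tracking$n_points
  method <- match.arg(config$tracking$method, c("fused", "bm", "snake"))

  init <- resample_closed(
    contour(init$points, pixel_spacing = spacing), n_pts)
  schedule <- config_schedule(config, nf)
  snake_par <- do.call(snake_params, config$snake)
  material <- do.call(material_params, config$material)

  state <- list(x_prev = init, x_prev2 = init, mean_shape = init,
                A1 = config$tracking$A1, A2 = config$tracking$A2)
  mean_sum <- init$points
  prev_out <- init
  results <- vector("list", nf - 1)
  areas <- numeric(nf)
  areas[1] <- polygon_area(init, units = "mm")

  for (k in seq(2, nf)) {
    kb <- k - 1                               # 0-based index of this frame
    pred <- predict_contour(state)
    p <- pressure_at_frame(kb - 1, schedule)  # load driving k-1 -> k
    phase <- if (p >= 0) "active" else "passive"

    bm <- NULL
    bm_diag <- NULL
    bm_err <- tryCatch({
      mesh <- triangulate_region(
        prev_out, target_edge = perimeter(prev_out) / config$mesh$n_boundary)
      mesh <- assemble_surface(mesh, config$mesh$basal_fraction)
      sol <- solve_deformation(mesh, material, p, phase = phase,
                               max_newton = config$solver$max_newton,
                               tol = config$solver$tol,
                               load_steps = config$solver$load_steps)
      bm <- resample_closed(
        deformed_boundary_contour(mesh, sol$u, pixel_spacing = spacing),
        n_pts)
      bm_diag <- list(newton_iterations = sol$iterations,
                      residual = sol$residual)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(bm_err) && method != "snake") {
      warning(sprintf("frame %d: BM solve failed (%s); using snake only",
                      kb, bm_err))
    }

    snake <- resample_closed(evolve_snake(pred, frames[[k]], snake_par),
                             n_pts)
    snake$pixel_spacing <- spacing

    fusion_diag <- NULL
    out <- if (method == "snake" || (method == "fused" && is.null(bm))) {
      snake
    } else if (method == "bm" && !is.null(bm)) {
      bm
    } else if (method == "bm") {
      snake                                    # BM failed: fall back
    } else {
      fu <- fuse(bm, snake, tol = config$fusion$tol,
                 max_iter = config$fusion$max_iter,
                 window = config$fusion$window)
      fusion_diag <- list(iterations = fu$iterations,
                          fallbacks = fu$fallbacks)
      fu$contour
    }

    areas[k] <- polygon_area(out, units = "mm")
    results[[k - 1]] <- list(
      frame = kb, bm_contour = bm, snake_contour = snake,
      fused_contour = if (method == "fused") out else NULL,
      contour = out, pressure_kpa = p, area_mm2 = areas[k],
      bm_diagnostics = bm_diag, fusion_diagnostics = fusion_diag)

    state$x_prev2 <- state$x_prev
    state$x_prev <- out
    mean_sum <- mean_sum + out$points
    state$mean_shape <- contour(mean_sum / k, pixel_spacing = spacing,
                                validate = FALSE)
    prev_out <- out
  }

  structure(list(results = results, areas_mm2 = areas,
                 ef = ejection_fraction(areas[1], min(areas)),
                 config = config),
            class = "lv_track_result")
}

#' @export
print.lv_track_result <- function(x, ...) {
  cat(sprintf(
    "lv_track_result: %d frames, ED area %.1f mm^2, ES area %.1f mm^2, EF %.1f%%\n",
    length(x$areas_mm2), x$areas_mm2[1], min(x$areas_mm2), x$ef))
  invisible(x)
}

#' Evaluate tracked contours against references
#'
#' Per-frame APD of each available method contour against the matching
#' reference contour, plus summary statistics in the layout of a
#' per-method mean +/- sd table, EF of both, and Bland-Altman agreement of
#' the per-frame areas.
#'
#' @param result an `lv_track_result`.
#' @param refs list of reference `lv_contour`s, one per frame (the frame-0
#'   reference is compared against the initial contour's area only).
#' @return list: `per_frame` data frame (frame, apd_fused/bm/snake, areas),
#'   `summary` (per-method mean and sd APD), `ef_pred`, `ef_ref`,
#'   `area_bland_altman`.
#' @export
evaluate_tracking <- function(result, refs) {
  res <- result$results
  nf <- length(res)
  stopifnot(length(refs) >= nf + 1)
  get_apd <- function(field) {
    vapply(seq_len(nf), function(i) {
      cc <- res[[i]][[field]]
      if (is.null(cc)) return(NA_real_)
      apd(cc, refs[[i + 1]])
    }, numeric(1))
  }
  per <- data.frame(
    frame = vapply(res, `[[`, numeric(1), "frame"),
    apd = get_apd("contour"),
    apd_bm = get_apd("bm_contour"),
    apd_snake = get_apd("snake_contour"),
    area_mm2 = vapply(res, `[[`, numeric(1), "area_mm2"),
    area_ref_mm2 = vapply(seq_len(nf), function(i)
      polygon_area(refs[[i + 1]], units = "mm"), numeric(1)))
  summ <- data.frame(
    method = c("tracked", "bm", "snake"),
    mean_apd_mm = c(mean(per$apd), mean(per$apd_bm), mean(per$apd_snake)),
    sd_apd_mm = c(stats::sd(per$apd), stats::sd(per$apd_bm),
                  stats::sd(per$apd_snake)))
  ref_areas <- c(polygon_area(refs[[1]], units = "mm"), per$area_ref_mm2)
  list(per_frame = per, summary = summ,
       ef_pred = result$ef,
       ef_ref = ejection_fraction(ref_areas[1], min(ref_areas)),
       area_bland_altman = bland_altman(result$areas_mm2, ref_areas))
}
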