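#' Default pipeline configuration
#'
#' Returns the full nested configuration with defaults; any supplied values
#' override the defaults (partial lists are merged). Heart-rate bands may be
#' given in bpm via `band_bpm`, which [validate_config()] converts to Hz
#' (bpm / 60).
#'
#' @param ... named overrides, e.g. `enhance = list(alpha = 25)`.
#' @return Nested list of class `flow_config`.
#' @export
flow_config <- function(...) {
  cfg <- list(
    stabilize = list(enabled = TRUE, reference_index = 1L, max_iters = 50L,
                     pyramid_levels = 3L),
    attenuate = list(enabled = FALSE, cutoff = 0.5),
    enhance = list(enabled = TRUE, alpha = 50, band = c(0.8, 3.0),
                   spatial_sigma = 3),
    centerline = list(downsample_factor = 25L, auto_factor = FALSE,
                      prune_spurs_px = 10L),
    signals = list(band = c(0.8, 3.0), stride = 2L),
    annotate = list(colour = "cyan", arrow_width_px = 2)
  )
  structure(merge_config(cfg, list(...)), class = "flow_config")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Validate a pipeline configuration
#'
#' Checks parameter sanity (band inside Nyquist, non-negative magnification,
#' positive downsampling factor, positive frame rate) and converts bpm
#' heart-rate bands to Hz. Returns the list of problems found (empty when
#' the configuration is usable) together with the normalised configuration.
#'
#' @param cfg a `flow_config` (or plain nested list; missing entries get
#'   defaults).
#' @param fps frame rate of the clip the configuration will be applied to
#'   (optional; enables Nyquist checks).
#' @return List with `problems` (character vector) and `config` (normalised
#'   `flow_config`).
#' @export
validate_config <- function(cfg = flow_config(), fps = NULL) {
  if (!inherits(cfg, "flow_config")) cfg <- do.call(flow_config, as.list(cfg))
  problems <- character(0)
  for (section in c("enhance", "signals")) {
    bb <- cfg[[section]]$band_bpm
    if (!is.null(bb)) {
      cfg[[section]]$band <- as.numeric(bb) / 60
      cfg[[section]]$band_bpm <- NULL
    }
    band <- cfg[[section]]$band
    if (band[1] <= 0 || band[1] >= band[2]) {
      problems <- c(problems, sprintf("%s: band must satisfy 0 < lo < hi", section))
    }
    if (!is.null(fps) && band[2] >= fps / 2) {
      problems <- c(problems, sprintf("%s: upper band >= Nyquist (fps/2 = %g Hz)",
                                      section, fps / 2))
    }
  }
  if (cfg$enhance$alpha < 0) problems <- c(problems, "enhance: alpha must be >= 0")
  if (cfg$centerline$downsample_factor < 1)
    problems <- c(problems, "centerline: downsample_factor must be >= 1")
  if (!is.null(fps) && fps <= 0) problems <- c(problems, "fps must be positive")
  list(problems = problems, config = cfg)
}

#' Infer blood-flow direction in a vessel from a short video
#'
#' The top-level fit: runs the full analysis on a clip and its vessel
#' segmentation - affine stabilization, Eulerian colour magnification in the
#' pulsatile band, centerline polyline extraction, per-vertex green-channel
#' signal averaging, heart-rate estimation, per-vertex Fourier phase, and
#' reliability-filtered phase-difference direction inference. The analysis
#' itself contains no randomness: identical inputs give identical results.
#'
#' @param clip a [video_clip].
#' @param mask a [vessel_mask] for the vessel under investigation.
#' @param config a [flow_config()].
#' @return Object of class `vesselflow`: list with `direction` (a
#'   `flow_direction`), `profile`, `signals`, `centerline`, `stabilization`
#'   (report or `NULL`), `reference_frame`, `config`, `fps`. Methods:
#'   `print`, `summary`, `coef` (per-pair phase differences), `plot`
#'   (annotated frame).
#' @examples
#' \donttest{
#' phantom <- generate_vessel_video(synth_config(duration = 4, fps = 30))
#' fit <- vesselflow(phantom$clip, phantom$mask,
#'                   config = flow_config(stabilize = list(enabled = FALSE)))
#' print(fit)
#' }
#' @export
vesselflow <- function(clip, mask, config = flow_config()) {
  stopifnot(inherits(clip, "video_clip"), inherits(mask, "vessel_mask"))
  check_mask_clip(mask, clip)
  v <- validate_config(config, fps = clip$fps)
  if (length(v$problems)) stop("invalid configuration:\n  ", paste(v$problems, collapse = "\n  "))
  cfg <- v$config
  stab_report <- NULL
  work <- clip
  if (isTRUE(cfg$stabilize$enabled)) {
    st <- stabilize_affine(work, reference_index = cfg$stabilize$reference_index,
                           mask = mask, max_iters = cfg$stabilize$max_iters,
                           pyramid_levels = cfg$stabilize$pyramid_levels)
    work <- st$clip
    stab_report <- st$report
  }
  if (isTRUE(cfg$attenuate$enabled)) {
    work <- attenuate_residual_motion(work, cutoff = cfg$attenuate$cutoff)
  }
  analysed <- work
  if (isTRUE(cfg$enhance$enabled)) {
    analysed <- magnify_colour(work, enhancement_config(
      alpha = cfg$enhance$alpha, band = cfg$enhance$band,
      spatial_sigma = cfg$enhance$spatial_sigma))
  }
  centerline <- extract_centerline(mask, k = cfg$centerline$downsample_factor,
                                   auto = cfg$centerline$auto_factor,
                                   prune_spurs_px = cfg$centerline$prune_spurs_px)
  vss <- extract_vertex_signals(analysed, mask, centerline)
  hr <- estimate_heart_rate(vss, band = cfg$signals$band)
  profile <- vertex_phase(vss, hr$heart_bin, stride = cfg$signals$stride)
  direction <- infer_direction(profile, direction_config(profile$f_heart, clip$fps))
  ref_idx <- if (isTRUE(cfg$stabilize$enabled)) cfg$stabilize$reference_index else mask$frame_index
  structure(list(direction = direction, profile = profile, signals = vss,
                 centerline = centerline, stabilization = stab_report,
                 reference_frame = clip$frames[, , , ref_idx, drop = TRUE],
                 config = cfg, fps = clip$fps),
            class = "vesselflow")
}

#' @export
print.vesselflow <- function(x, ...) {
  d <- x$direction
  cat("Blood-flow direction analysis\n")
  cat(sprintf("  heart rate: %.3f Hz (%.1f bpm)\n", d$f_heart, d$f_heart * 60))
  cat(sprintf("  vertices: %d (polyline), %d sampled\n",
              nrow(x$centerline$vertices), length(x$profile$theta)))
  cat(sprintf("  pairs: %d accepted of %d\n", d$n_accepted, nrow(d$pairs)))
  if (d$overall == "indeterminate") {
    cat("  overall direction: indeterminate (no reliable phase differences)\n")
  } else {
    cat(sprintf("  overall direction: %s, from (%.0f, %.0f) toward (%.0f, %.0f) [row, col]\n",
                d$overall, d$upstream[1], d$upstream[2],
                d$downstream[1], d$downstream[2]))
  }
  invisible(x)
}

#' @export
summary.vesselflow <- function(object, ...) {
  structure(list(fit = object), class = "summary.vesselflow")
}

#' @export
print.summary.vesselflow <- function(x, ...) {
  print(x$fit)
  cat("\nPer-pair phase differences:\n")
  p <- x$fit$direction$pairs
  print(data.frame(pair = sprintf("v%d-v%d", p$vertex_a, p$vertex_b),
                   dtheta = round(p$dtheta, 4), status = p$status,
                   direction = p$direction), row.names = FALSE)
  cat(sprintf("\nReliability window: %.4f <= |dtheta| <= %.4f rad\n",
              x$fit$direction$lower_bound, pi))
  invisible(x)
}

#' @export
coef.vesselflow <- function(object, ...) {
  p <- object$direction$pairs
  stats::setNames(p$dtheta, sprintf("v%d-v%d", p$vertex_a, p$vertex_b))
}

#' @export
plot.vesselflow <- function(x, y, ...) {
  mask_mat <- matrix(FALSE, dim(x$reference_frame)[1], dim(x$reference_frame)[2])
  ann <- render_arrows(x$reference_frame, x$direction, x$centerline,
                       colour = x$config$annotate$colour,
                       width = x$config$annotate$arrow_width_px)
  op <- graphics::par(mar = c(0, 0, 2, 0))
  on.exit(graphics::par(op))
  graphics::plot(c(0, 1), c(0, 1), type = "n", axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("flow: %s", x$direction$overall), asp = dim(ann$image)[1] / dim(ann$image)[2])
  graphics::rasterImage(grDevices::as.raster(ann$image), 0, 0, 1, 1)
  invisible(ann)
}

#' Run the end-to-end pipeline from files
#'
#' Reads the clip and mask, runs [vesselflow()], and writes machine-readable
#' artifacts to the output directory: `result.json` (per-pair records,
#' heart rate, overall direction), `annotated.png`, `phase_map.png`, and
#' `stabilization.json` when stabilization ran. Indeterminate direction is a
#' normal outcome, not an error.
#'
#' @param input directory of numbered frames (see [read_clip()]), or a
#'   [video_clip].
#' @param mask mask PNG path, or a [vessel_mask].
#' @param fps frame rate in Hz (required when `input` is a path).
#' @param output_dir directory for artifacts (`NULL` writes nothing).
#' @param config a [flow_config()].
#' @return The `vesselflow` fit, invisibly.
#' @export
run_pipeline <- function(input, mask, fps = NULL, output_dir = NULL,
                         config = flow_config()) {
  t0 <- proc.time()[["elapsed"]]
  clip <- if (inherits(input, "video_clip")) input else read_clip(input, fps_override = fps)
  msk <- if (inherits(mask, "vessel_mask")) mask else read_mask(mask, clip)
  fit <- vesselflow(clip, msk, config = config)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    d <- fit$direction
    res <- list(
      overall = d$overall,
      upstream = d$upstream, downstream = d$downstream,
      f_heart_hz = d$f_heart, f_video_hz = d$f_video,
      lower_bound_rad = d$lower_bound,
      n_accepted = d$n_accepted,
      pairs = d$pairs,
      polyline = list(vertices = unname(fit$centerline$vertices),
                      downsample_factor = fit$centerline$downsample_factor,
                      coordinates = "1-based (row, col)")
    )
    jsonlite::write_json(res, file.path(output_dir, "result.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    ann <- render_arrows(fit$reference_frame, d, fit$centerline,
                         colour = config$annotate$colour,
                         width = config$annotate$arrow_width_px)
    write_annotation(ann, file.path(output_dir, "annotated.png"))
    pm <- render_phase_map(fit$reference_frame, msk, fit$profile)
    write_annotation(pm, file.path(output_dir, "phase_map.png"))
    if (!is.null(fit$stabilization)) {
      jsonlite::write_json(list(params = fit$stabilization$params,
                                residual_before = fit$stabilization$residual_before,
                                residual_after = fit$stabilization$residual_after,
                                diverged = fit$stabilization$diverged),
                           file.path(output_dir, "stabilization.json"),
                           digits = NA, matrix = "rowmajor")
    }
    message(sprintf("pipeline finished in %.1f s: %s",
                    proc.time()[["elapsed"]] - t0, d$overall))
  }
  invisible(fit)
}
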