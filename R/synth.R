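#' Synthetic phantom configuration
#'
#' Parameters of the software phantom: a curved tube whose green channel
#' carries a propagating periodic pulse wave, emulating a silicone vessel
#' phantom driven by a pump that is on for 1/3 s and off for 2/3 s of every
#' 1 s cycle (approximating systolic/diastolic time fractions), filled with
#' red-dyed water. The pulse *decreases* the green channel (blood-volume
#' increase raises oxyhemoglobin absorption); direction inference is
#' sign-agnostic since it uses relative phase only.
#'
#' @param width,height frame size in px.
#' @param fps frame rate in Hz (60 as for the phantom recordings; clinical
#'   microscopes record at 30).
#' @param duration clip length in seconds (default 8, within the 5-10 s a
#'   surgeon can hold the scene still).
#' @param geometry `"straight"` or `"s_curve"`.
#' @param from,to curve endpoints, `(row, col)`.
#' @param curve_amplitude perpendicular amplitude of the S-curve in px.
#' @param radius tube radius in px (>= 2).
#' @param period pump period in s (default 1.0).
#' @param on_fraction fraction of the period the pump is on (default 1/3).
#' @param smooth_sigma Gaussian smoothing of the pump edges in s (default
#'   0.05; 0 reproduces a hard on/off cycle).
#' @param wave_speed propagation speed of the pulse along the vessel, px/s.
#' @param pulse_amplitude green-channel dip amplitude (default 0.05).
#' @param baseline_vessel,baseline_background RGB triples in \[0, 1\].
#' @param noise_sigma per-pixel Gaussian noise s.d.
#' @param jitter_px amplitude of slow global translational camera jitter in
#'   px (0 disables).
#' @param upstream which geometric end the pulse enters from: `"start"`
#'   (the `from` end) or `"end"`.
#' @param seed RNG seed, recorded in the ground-truth metadata.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(width = 120L, height = 80L, fps = 60, duration = 8,
                         geometry = c("straight", "s_curve"),
                         from = c(height / 2, 10), to = c(height / 2, width - 10),
                         curve_amplitude = height / 5, radius = 6,
                         period = 1.0, on_fraction = 1 / 3, smooth_sigma = 0.05,
                         wave_speed = 150, pulse_amplitude = 0.05,
                         baseline_vessel = c(0.70, 0.50, 0.45),
                         baseline_background = c(0.30, 0.30, 0.30),
                         noise_sigma = 0.005, jitter_px = 0,
                         upstream = c("start", "end"), seed = 1L) {
  geometry <- match.arg(geometry)
  upstream <- match.arg(upstream)
  stopifnot(on_fraction > 0, on_fraction < 1, wave_speed > 0, radius >= 2,
            period > 0, fps > 0, duration > 0)
  if (period < 2 / fps) stop("pump period unresolvable at this frame rate")
  structure(as.list(environment()), class = "synth_config")
}

#' Pump drive waveform
#'
#' Periodic rectangular drive with period `period` and duty cycle
#' `on_fraction`, optionally convolved with a Gaussian of width
#' `smooth_sigma` seconds (closed form via the Gaussian CDF). Smoothing
#' concentrates energy in the fundamental so the heart-rate estimator locks
#' onto the pump period; `smooth_sigma = 0` gives the hard on/off cycle.
#'
#' @param t time(s) in seconds (vectorised).
#' @param period pump period, s.
#' @param on_fraction duty cycle in (0, 1).
#' @param smooth_sigma Gaussian edge smoothing, s.
#' @return Drive values in \[0, 1\], same length as `t`.
#' @export
pump_waveform <- function(t, period = 1.0, on_fraction = 1 / 3, smooth_sigma = 0) {
  stopifnot(period > 0, on_fraction > 0, on_fraction < 1)
  if (smooth_sigma <= 0) {
    return(as.numeric((t %% period) < on_fraction * period))
  }
  on <- on_fraction * period
  n0 <- floor(min(t) / period) - 3L
  n1 <- floor(max(t) / period) + 3L
  out <- numeric(length(t))
  for (n in n0:n1) {
    out <- out + stats::pnorm((t - n * period) / smooth_sigma) -
                 stats::pnorm((t - n * period - on) / smooth_sigma)
  }
  pmin(pmax(out, 0), 1)
}

# dense centre curve of the phantom, sampled at ~0.25 px chord steps,
# with cumulative arclength
synth_curve <- function(cfg) {
  chord <- sqrt(sum((cfg$to - cfg$from)^2))
  n <- max(2L, ceiling(chord / 0.25) * 2L)
  u <- seq(0, 1, length.out = n)
  base_r <- cfg$from[1] + u * (cfg$to[1] - cfg$from[1])
  base_c <- cfg$from[2] + u * (cfg$to[2] - cfg$from[2])
  if (cfg$geometry == "s_curve") {
    tang <- (cfg$to - cfg$from) / chord
    norm <- c(-tang[2], tang[1])
    off <- cfg$curve_amplitude * sin(2 * pi * u)
    base_r <- base_r + off * norm[1]
    base_c <- base_c + off * norm[2]
  }
  s <- c(0, cumsum(sqrt(diff(base_r)^2 + diff(base_c)^2)))
  list(r = base_r, c = base_c, s = s, length = s[n])
}

#' Generate a synthetic vessel video with known flow direction
#'
#' Renders the software phantom: the vessel mask is the set of pixels within
#' `radius` of the centre curve; the green channel at arclength `s` and time
#' `t` is `baseline_green - pulse_amplitude * pump(t - s/wave_speed)` (with
#' `s` measured from the upstream end), the red channel is elevated, and
#' per-pixel Gaussian noise plus optional slow global translational jitter
#' are added. All ground truth (direction, wave speed, curve arclength,
#' seed) is recorded in the returned metadata. Same seed, same clip:
#' generation is fully deterministic.
#'
#' @param cfg a [synth_config()].
#' @return List with `clip` (a [video_clip]), `mask` (a [vessel_mask]) and
#'   `truth` (ground-truth metadata: `direction` - `"forward"` means the
#'   pulse travels from the `from` end toward the `to` end -, `upstream_end`
#'   coordinates, `wave_speed`, `curve` with dense samples and arclength,
#'   pump parameters, `seed`).
#' @export
generate_vessel_video <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  H <- as.integer(cfg$height); W <- as.integer(cfg$width)
  T <- round(cfg$duration * cfg$fps)
  curve <- synth_curve(cfg)
  if (min(curve$r) < cfg$radius + 1 || max(curve$r) > H - cfg$radius ||
      min(curve$c) < cfg$radius + 1 || max(curve$c) > W - cfg$radius)
    stop("tube leaves the frame; shrink the curve or the radius")
  grid <- expand_grid_rc(H, W)
  # nearest curve sample per pixel, chunked to bound memory
  best_d2 <- rep(Inf, H * W); best_i <- rep(1L, H * W)
  idx <- seq_along(curve$r)
  for (chunk in split(idx, ceiling(idx / 500))) {
    d2 <- outer(grid$r, curve$r[chunk], "-")^2 + outer(grid$c, curve$c[chunk], "-")^2
    mi <- max.col(-d2, ties.method = "first")
    md <- d2[cbind(seq_len(H * W), mi)]
    upd <- md < best_d2
    best_d2[upd] <- md[upd]; best_i[upd] <- chunk[mi[upd]]
  }
  vessel <- best_d2 <= cfg$radius^2
  mask <- vessel_mask(matrix(vessel, H, W))
  s_px <- curve$s[best_i[vessel]]
  if (cfg$upstream == "end") s_px <- curve$length - s_px
  tt <- (seq_len(T) - 1) / cfg$fps
  # pulse drive per vessel pixel per frame
  drive <- matrix(pump_waveform(rep(tt, each = length(s_px)) - s_px / cfg$wave_speed,
                                cfg$period, cfg$on_fraction, cfg$smooth_sigma),
                  length(s_px), T)
  frames <- array(0, c(H, W, 3L, T))
  for (ch in 1:3) {
    base <- matrix(cfg$baseline_background[ch], H, W)
    base[vessel] <- cfg$baseline_vessel[ch]
    frames[, , ch, ] <- base
  }
  gidx <- which(vessel) + H * W                      # green-channel offsets
  for (t in seq_len(T)) {
    frames[, , , t][gidx] <- cfg$baseline_vessel[2] - cfg$pulse_amplitude * drive[, t]
  }
  jitter <- NULL
  if (cfg$jitter_px > 0) {
    ph <- stats::runif(2, 0, 2 * pi)
    jr <- cfg$jitter_px * (sin(2 * pi * 0.30 * tt + ph[1]) - sin(ph[1]))
    jc <- cfg$jitter_px * (sin(2 * pi * 0.25 * tt + ph[2]) - sin(ph[2]))
    jitter <- cbind(row = jr, col = jc)
    for (t in seq_len(T)) {
      if (abs(jr[t]) + abs(jc[t]) < 1e-9) next
      p <- c(0, 0, 0, 0, jc[t], jr[t])               # pure translation affine
      frames[, , , t] <- warp_affine_frame(frames[, , , t, drop = TRUE], p)
    }
  }
  if (cfg$noise_sigma > 0) {
    frames <- frames + stats::rnorm(length(frames), 0, cfg$noise_sigma)
  }
  frames[frames < 0] <- 0; frames[frames > 1] <- 1
  clip <- video_clip(frames, fps = cfg$fps)
  truth <- list(
    direction = if (cfg$upstream == "start") "forward" else "backward",
    upstream_end = if (cfg$upstream == "start") c(curve$r[1], curve$c[1])
                   else c(curve$r[length(curve$r)], curve$c[length(curve$c)]),
    wave_speed = cfg$wave_speed,
    pump = list(period = cfg$period, on_fraction = cfg$on_fraction,
                smooth_sigma = cfg$smooth_sigma),
    pulse_amplitude = cfg$pulse_amplitude, noise_sigma = cfg$noise_sigma,
    jitter = jitter, fps = cfg$fps, duration = cfg$duration,
    curve = curve, seed = cfg$seed
  )
  list(clip = clip, mask = mask, truth = truth)
}

#' True pulse-wave delay between two image points
#'
#' Ground-truth travel time of the pulse between two points, from the
#' phantom metadata: the difference of their (upstream-measured) arclengths
#' divided by the wave speed. Positive when `b` is downstream of `a`.
#'
#' @param truth metadata from [generate_vessel_video()].
#' @param a,b points `(row, col)`.
#' @return Delay in seconds.
#' @export
true_delay <- function(truth, a, b) {
  s <- function(p) {
    i <- which.min((truth$curve$r - p[1])^2 + (truth$curve$c - p[2])^2)
    sp <- truth$curve$s[i]
    if (truth$direction == "backward") truth$curve$length - sp else sp
  }
  (s(b) - s(a)) / truth$wave_speed
}

#' Compare an inferred direction with phantom ground truth
#'
#' Polyline vertex order depends on where the skeleton scan started, so
#' `"forward"`/`"backward"` labels are not comparable across runs; the
#' physical direction is. Correctness is judged by which geometric end of
#' the vessel the result places upstream.
#'
#' @param result a `flow_direction` (or a `vesselflow` fit).
#' @param truth metadata from [generate_vessel_video()].
#' @return `TRUE` (correct), `FALSE` (reversed), or `NA` (indeterminate).
#' @export
direction_correct <- function(result, truth) {
  if (inherits(result, "vesselflow")) result <- result$direction
  if (result$overall == "indeterminate") return(NA)
  cu <- truth$upstream_end
  n <- length(truth$curve$r)
  other <- if (all(cu == c(truth$curve$r[1], truth$curve$c[1])))
    c(truth$curve$r[n], truth$curve$c[n]) else c(truth$curve$r[1], truth$curve$c[1])
  du <- sum((result$upstream - cu)^2)
  dd <- sum((result$upstream - other)^2)
  du < dd
}
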