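#' Direction-inference configuration
#'
#' Bundles the two frequencies that define the reliability window for a
#' phase difference: the heart rate `f_heart` and the video frame rate
#' `f_video`. The smallest reliably detectable phase shift between two
#' points is `2*pi*f_heart/f_video` (one frame of delay at the heart-rate
#' frequency); differences larger than `pi` are rejected as phase wrapping.
#'
#' @param f_heart heart-rate frequency in Hz.
#' @param f_video video frame rate in Hz; must exceed `2 * f_heart`.
#' @return List of class `direction_config`.
#' @export
direction_config <- function(f_heart, f_video) {
  stopifnot(f_heart > 0, f_video > 0)
  if (f_video <= 2 * f_heart)
    stop("frame rate must exceed twice the heart rate (Nyquist)")
  structure(list(f_heart = f_heart, f_video = f_video),
            class = "direction_config")
}

#' Phase differences between consecutive sampled vertices
#'
#' Raw differences `theta[i+1] - theta[i]` of the principal-value phases of
#' consecutive sampled vertices, reported in `(-2*pi, 2*pi)`. No unwrapping
#' is applied: an apparent jump across the `+/-pi` boundary produces a
#' difference with magnitude above `pi`, which the reliability filter then
#' detects and rejects rather than corrects.
#'
#' @param profile a `phase_profile` with at least 2 sampled vertices.
#' @return Numeric vector of length `V_sampled - 1`.
#' @export
phase_differences <- function(profile) {
  stopifnot(inherits(profile, "phase_profile"))
  if (length(profile$theta) < 2L) stop("need at least 2 sampled vertices")
  diff(profile$theta)
}

#' Reliability filter for a phase difference
#'
#' Accepts a phase difference as a reliable measure of pulse-wave delay iff
#' `2*pi*f_heart/f_video <= |dtheta| <= pi`. Below the lower bound the shift
#' is smaller than the camera can resolve (`too_small`, likely noise); above
#' `pi` it is attributed to phase wrapping (`wrapped`).
#'
#' @param dtheta phase difference(s), radians.
#' @param cfg a [direction_config()].
#' @return Character vector: `"accepted"`, `"too_small"` or `"wrapped"`.
#' @export
reliability_filter <- function(dtheta, cfg) {
  stopifnot(inherits(cfg, "direction_config"))
  lower <- 2 * pi * cfg$f_heart / cfg$f_video
  ifelse(abs(dtheta) > pi, "wrapped",
         ifelse(abs(dtheta) >= lower, "accepted", "too_small"))
}

#' Infer blood-flow direction from a phase profile
#'
#' For each pair of consecutive sampled vertices, computes the phase
#' difference, applies the reliability window, and - for accepted pairs -
#' assigns a direction from the higher-phase vertex to the lower-phase
#' vertex (phase decreases along the direction of pulse-wave travel). The
#' overall direction is the unweighted majority vote of the accepted pairs;
#' with no accepted pairs, or a tie, the result is `indeterminate` - an
#' explicit, honest outcome rather than an error.
#'
#' @param profile a `phase_profile`.
#' @param cfg a [direction_config()]; defaults to the profile's own
#'   `f_heart` and `fps`.
#' @return Object of class `flow_direction`: list with `pairs` (data frame:
#'   vertex indices, coordinates, `dtheta`, `status`, `direction` in
#'   `"forward"` / `"backward"` / `"none"`, where forward means from the
#'   first polyline vertex toward the last), `overall`, `n_accepted`,
#'   `upstream`, `downstream` (coordinates of the inferred upstream and
#'   downstream polyline endpoints, `NA` when indeterminate), `f_heart`,
#'   `f_video`, `lower_bound`.
#' @export
infer_direction <- function(profile, cfg = NULL) {
  stopifnot(inherits(profile, "phase_profile"))
  if (is.null(cfg)) cfg <- direction_config(profile$f_heart, profile$fps)
  dtheta <- phase_differences(profile)
  status <- reliability_filter(dtheta, cfg)
  np <- length(dtheta)
  direction <- rep("none", np)
  acc <- status == "accepted"
  direction[acc] <- ifelse(dtheta[acc] < 0, "forward", "backward")
  pairs <- data.frame(
    vertex_a = profile$sampled_idx[seq_len(np)],
    vertex_b = profile$sampled_idx[seq_len(np) + 1L],
    row_a = profile$vertices[seq_len(np), 1],
    col_a = profile$vertices[seq_len(np), 2],
    row_b = profile$vertices[seq_len(np) + 1L, 1],
    col_b = profile$vertices[seq_len(np) + 1L, 2],
    theta_a = profile$theta[seq_len(np)],
    theta_b = profile$theta[seq_len(np) + 1L],
    dtheta = dtheta,
    status = status,
    direction = direction,
    stringsAsFactors = FALSE
  )
  nf <- sum(direction == "forward"); nb <- sum(direction == "backward")
  overall <- if (nf > nb) "forward" else if (nb > nf) "backward" else "indeterminate"
  ends <- profile$vertices[c(1L, nrow(profile$vertices)), , drop = FALSE]
  upstream <- downstream <- c(NA_real_, NA_real_)
  if (overall == "forward") { upstream <- ends[1, ]; downstream <- ends[2, ] }
  if (overall == "backward") { upstream <- ends[2, ]; downstream <- ends[1, ] }
  structure(list(pairs = pairs, overall = overall,
                 n_accepted = sum(acc),
                 upstream = as.numeric(upstream), downstream = as.numeric(downstream),
                 f_heart = cfg$f_heart, f_video = cfg$f_video,
                 lower_bound = 2 * pi * cfg$f_heart / cfg$f_video),
            class = "flow_direction")
}

#' @export
print.flow_direction <- function(x, ...) {
  cat(sprintf("<flow_direction> overall: %s (%d/%d pairs accepted, f_heart = %.3f Hz)\n",
              x$overall, x$n_accepted, nrow(x$pairs), x$f_heart))
  invisible(x)
}
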