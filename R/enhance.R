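#' Enhancement configuration
#'
#' Parameters of the Eulerian colour magnification step. `alpha` is the
#' dimensionless magnification factor applied to the band-passed colour
#' deviation; the band (Hz) selects the pulsatile frequencies to amplify
#' (default 0.8-3 Hz, wide enough to cover intraoperative heart rates outside
#' the normal 60-100 bpm range); `spatial_sigma` is a Gaussian blur (px)
#' applied to the deviation before amplification, standing in for the spatial
#' decomposition of full Eulerian magnification.
#'
#' @param alpha magnification factor (>= 0, default 50).
#' @param band numeric length-2, `(f_lo, f_hi)` in Hz.
#' @param spatial_sigma Gaussian sigma in px (0 disables).
#' @param channels colour channels to amplify (default all three).
#' @return A list of class `enhancement_config`.
#' @export
enhancement_config <- function(alpha = 50, band = c(0.8, 3.0),
                               spatial_sigma = 3, channels = 1:3) {
  stopifnot(alpha >= 0, length(band) == 2L, band[1] > 0, band[1] < band[2],
            spatial_sigma >= 0, all(channels %in% 1:3))
  structure(list(alpha = alpha, band = as.numeric(band),
                 spatial_sigma = spatial_sigma, channels = as.integer(channels)),
            class = "enhancement_config")
}

#' Ideal temporal band-pass filter
#'
#' Brick-wall frequency-domain filter: the discrete Fourier coefficients
#' whose frequencies lie inside `[f_lo, f_hi]` (inclusive) are kept, all
#' others - including DC - are zeroed, and the series is transformed back.
#' Operates on a vector or column-wise on a matrix (time along rows). The
#' filter is an orthogonal projection, hence idempotent, and a pure sinusoid
#' whose frequency falls on an in-band DFT bin passes through unchanged
#' except for mean removal.
#'
#' @param x numeric vector (length T) or matrix (T x n series).
#' @param fps sampling rate in Hz.
#' @param band numeric `(f_lo, f_hi)` in Hz, inside `(0, fps/2)`.
#' @return Filtered series, same shape as `x`.
#' @export
temporal_bandpass <- function(x, fps, band) {
  v <- is.null(dim(x))
  m <- if (v) matrix(x, ncol = 1L) else x
  T <- nrow(m)
  if (T < 4L) stop("series too short for band-pass filtering")
  if (band[1] <= 0 || band[2] >= fps / 2) stop("band must lie inside (0, fps/2)")
  keep <- bandpass_keep(T, fps, band)
  if (!any(keep)) {
    out <- m * 0
  } else {
    F <- stats::mvfft(m)
    F[!keep, ] <- 0
    out <- Re(stats::mvfft(F, inverse = TRUE)) / T
  }
  if (v) drop(out) else out
}

# logical index over DFT bins 0..T-1 whose |frequency| is within band
bandpass_keep <- function(T, fps, band) {
  k <- 0:(T - 1)
  f <- pmin(k, T - k) * fps / T          # absolute frequency of each bin
  f >= band[1] & f <= band[2]
}

#' Eulerian colour magnification of a video clip
#'
#' Amplifies subtle periodic colour changes: with `I` the per-pixel temporal
#' mean (reference frame), the deviation `I_t - I` is band-pass filtered to
#' the configured frequency range, optionally blurred spatially, scaled by
#' `alpha`, and added back to each frame. Output frames are clipped to
#' \[0, 1\]; the un-clipped band-passed deviation stack is retained so that
#' downstream signal analysis is never corrupted by clipping. An in-band
#' pure sinusoid is amplified exactly `(1 + alpha)`-fold (with
#' `spatial_sigma = 0`); out-of-band content is left untouched.
#'
#' @param clip a [video_clip] of duration at least `2 / f_lo` seconds.
#' @param cfg an [enhancement_config()].
#' @return Object of class `enhanced_clip`: list with `frames` (clipped,
#'   amplified), `delta` (band-passed deviation stack), `reference`
#'   (per-pixel temporal mean frame), `input` (the original frames), `alpha`,
#'   `band`, `fps`.
#' @export
magnify_colour <- function(clip, cfg = enhancement_config()) {
  stopifnot(inherits(clip, "video_clip"))
  if (clip_duration(clip) < 2 / cfg$band[1])
    stop(sprintf("clip too short for the band: need >= %.1f s (2 periods of %.2f Hz)",
                 2 / cfg$band[1], cfg$band[1]))
  d <- dim(clip$frames)
  H <- d[1]; W <- d[2]; T <- d[4]
  reference <- apply_temporal_mean(clip$frames)
  delta <- array(0, d)
  for (ch in cfg$channels) {
    x <- matrix(clip$frames[, , ch, ], H * W, T)       # pixels x time
    x <- sweep(x, 1L, as.vector(reference[, , ch]))
    x <- t(temporal_bandpass(t(x), clip$fps, cfg$band)) # filter along time
    dch <- array(x, c(H, W, T))
    if (cfg$spatial_sigma > 0) {
      dch <- EBImage::gblur(dch, sigma = cfg$spatial_sigma)
    }
    delta[, , ch, ] <- dch
  }
  frames <- clip$frames + cfg$alpha * delta
  frames[frames < 0] <- 0
  frames[frames > 1] <- 1
  structure(list(frames = frames, delta = delta, reference = reference,
                 input = clip$frames, alpha = cfg$alpha, band = cfg$band,
                 fps = clip$fps),
            class = "enhanced_clip")
}

# per-pixel temporal mean frame, H x W x 3
apply_temporal_mean <- function(frames) {
  d <- dim(frames)
  array(rowMeans(matrix(frames, prod(d[1:3]), d[4])), d[1:3])
}

#' @export
print.enhanced_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<enhanced_clip> %d x %d px, %d frames @ %g fps, alpha = %g, band %.2f-%.2f Hz\n",
              d[1], d[2], d[4], x$fps, x$alpha, x$band[1], x$band[2]))
  invisible(x)
}
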