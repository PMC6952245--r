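#' Extract per-vertex green-channel time series
#'
#' Partitions the mask's foreground pixels among the centerline vertices by
#' nearest-neighbour assignment (Euclidean distance in pixels; ties go to the
#' lower vertex index) and averages, per frame, the green-channel intensity
#' of each vertex's pixels. The green channel is used exclusively because
#' oxyhemoglobin absorption peaks in the green range, making it the most
#' sensitive channel to pulsatile blood volume. When given an
#' `enhanced_clip`, the un-clipped amplified signal path
#' (`input + alpha * delta`) is analysed so that display clipping never
#' distorts the waveforms.
#'
#' @param clip a [video_clip] or an `enhanced_clip` from [magnify_colour()].
#' @param mask a [vessel_mask]; only its foreground pixels participate.
#' @param polyline a `centerline_polyline` whose vertices lie inside the mask.
#' @return Object of class `vertex_signals`: list with `signals` (V x T
#'   matrix), `vertex_pixel_counts`, `vertices` (V x 2 coords), `fps`,
#'   `assignment` (per-mask-pixel vertex index, same order as
#'   `which(mask$mask)`).
#' @export
extract_vertex_signals <- function(clip, mask, polyline) {
  stopifnot(inherits(polyline, "centerline_polyline"))
  if (inherits(clip, "enhanced_clip")) {
    H <- dim(clip$frames)[1]; W <- dim(clip$frames)[2]; T <- dim(clip$frames)[4]
    g <- matrix(clip$input[, , 2, ] + clip$alpha * clip$delta[, , 2, ], H * W, T)
    fps <- clip$fps
  } else {
    stopifnot(inherits(clip, "video_clip"))
    d <- dim(clip$frames)
    H <- d[1]; W <- d[2]; T <- d[4]
    g <- matrix(clip$frames[, , 2, ], H * W, T)
    fps <- clip$fps
  }
  if (nrow(mask$mask) != H || ncol(mask$mask) != W)
    stop("mask dimensions do not match clip")
  V <- nrow(polyline$vertices)
  px <- which(mask$mask, arr.ind = TRUE)           # row-major? arr.ind gives (row,col)
  inside <- mask$mask[polyline$vertices]
  if (!all(inside))
    warning(sprintf("%d polyline vertices lie outside the mask", sum(!inside)))
  # nearest vertex per mask pixel; ties to the lower vertex index
  d2 <- outer(px[, 1], polyline$vertices[, 1], "-")^2 +
        outer(px[, 2], polyline$vertices[, 2], "-")^2
  assignment <- max.col(-d2, ties.method = "first")
  counts <- tabulate(assignment, nbins = V)
  if (any(counts == 0L))
    warning(sprintf("%d vertices have no assigned pixels and are excluded",
                    sum(counts == 0L)))
  lin <- px[, 1] + (px[, 2] - 1L) * H               # column-major linear index
  sums <- rowsum(g[lin, , drop = FALSE], assignment, reorder = TRUE)
  signals <- matrix(NA_real_, V, T)
  signals[sort(unique(assignment)), ] <- sums / counts[sort(unique(assignment))]
  structure(list(signals = signals, vertex_pixel_counts = counts,
                 vertices = polyline$vertices, fps = fps,
                 assignment = assignment),
            class = "vertex_signals")
}

#' @export
print.vertex_signals <- function(x, ...) {
  cat(sprintf("<vertex_signals> %d vertices x %d frames @ %g fps (%d mask px)\n",
              nrow(x$signals), ncol(x$signals), x$fps, sum(x$vertex_pixel_counts)))
  invisible(x)
}

#' Estimate the heart rate from the vessel's average signal
#'
#' Averages all vertex signals into a single series, takes its discrete
#' Fourier transform (rectangular window, no zero-padding), and returns the
#' frequency of the bin with the highest magnitude among bins whose
#' frequency lies inside the search band (DC excluded). The heart-rate
#' frequency therefore snaps to an exact DFT bin, with resolution
#' `fps / T` Hz. The dominant in-band component is assumed to be cardiac.
#'
#' @param vss a `vertex_signals` object.
#' @param band search band `(f_lo, f_hi)` in Hz (default 0.8-3).
#' @return List with `f_heart` (Hz), `heart_bin` (integer DFT bin index,
#'   where bin `k` has frequency `k * fps / T`), `spectrum` (magnitudes of
#'   bins 1..floor(T/2)).
#' @export
estimate_heart_rate <- function(vss, band = c(0.8, 3.0)) {
  stopifnot(inherits(vss, "vertex_signals"))
  T <- ncol(vss$signals)
  fps <- vss$fps
  avg <- colMeans(vss$signals, na.rm = TRUE)
  F <- stats::fft(avg - mean(avg))
  k <- seq_len(floor(T / 2))                 # positive-frequency bins
  f <- k * fps / T
  mag <- Mod(F[k + 1L])
  in_band <- f >= band[1] & f <= band[2]
  if (!any(in_band)) stop("no in-band component: clip too short for the search band")
  if (max(mag[in_band]) <= 1e-12 * T)
    stop("no in-band component: signal has no periodic content in the band")
  kb <- k[in_band][which.max(mag[in_band])]
  list(f_heart = kb * fps / T, heart_bin = kb, spectrum = mag)
}

#' Per-vertex Fourier phase at the heart-rate frequency
#'
#' For every `stride`-th polyline vertex (starting at the first), computes
#' the phase angle of the vertex signal's DFT coefficient at the heart-rate
#' bin, writing the coefficient as `Z = |Z| exp(j * theta)` with
#' `theta` in `[-pi, pi]`. The DFT sign convention is fixed so that a signal
#' delayed by `dt` seconds has its phase changed by `-2*pi*f*dt`: phase
#' decreases along the direction of pulse-wave travel.
#'
#' @param vss a `vertex_signals` object.
#' @param heart_bin DFT bin index from [estimate_heart_rate()].
#' @param stride sample every `stride`-th vertex (default 2, i.e. every
#'   second vertex).
#' @return Object of class `phase_profile`: list with `f_heart`, `heart_bin`,
#'   `sampled_idx` (polyline vertex indices used), `theta` (radians, one per
#'   sampled vertex), `vertices` (their coordinates), `fps`.
#' @export
vertex_phase <- function(vss, heart_bin, stride = 2L) {
  stopifnot(inherits(vss, "vertex_signals"))
  T <- ncol(vss$signals)
  if (heart_bin < 1L || heart_bin > floor(T / 2))
    stop("invalid heart-rate bin")
  V <- nrow(vss$signals)
  idx <- seq(1L, V, by = as.integer(stride))
  ok <- idx[!is.na(vss$signals[idx, 1])]
  if (length(ok) < length(idx))
    warning("sampled vertices without signal were dropped")
  theta <- vapply(ok, function(v) {
    Arg(stats::fft(vss$signals[v, ])[heart_bin + 1L])
  }, numeric(1))
  structure(list(f_heart = heart_bin * vss$fps / T, heart_bin = as.integer(heart_bin),
                 sampled_idx = ok, theta = theta,
                 vertices = vss$vertices[ok, , drop = FALSE], fps = vss$fps),
            class = "phase_profile")
}

#' @export
print.phase_profile <- function(x, ...) {
  cat(sprintf("<phase_profile> f_heart = %.3f Hz (bin %d), %d sampled vertices\n",
              x$f_heart, x$heart_bin, length(x$theta)))
  invisible(x)
}
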