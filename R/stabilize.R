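#' Stabilize a clip by affine registration to a reference frame
#'
#' Removes global camera/scene motion: every frame is registered to the
#' reference frame with a 6-parameter affine transform estimated by
#' differential (gradient-based, Gauss-Newton) motion estimation on a
#' 3-level coarse-to-fine pyramid, then warped to the reference geometry
#' with bilinear interpolation and edge replication. If a frame's residual
#' (mean absolute intensity difference to the reference, within the
#' dilated-mask region when a mask is given) grows instead of shrinking,
#' estimation is deemed divergent: a warning is emitted and the frame passes
#' through unwarped.
#'
#' @param clip a [video_clip].
#' @param reference_index 1-based reference frame (default 1, where the
#'   segmentation is drawn).
#' @param mask optional [vessel_mask]; residuals are then evaluated within
#'   the mask dilated by 5 px.
#' @param max_iters Gauss-Newton iterations per pyramid level (default 50).
#' @param pyramid_levels number of pyramid levels (default 3).
#' @param tol convergence threshold on the parameter update (default 1e-4).
#' @return List with `clip` (stabilized [video_clip]) and `report` (class
#'   `stabilization_report`): per-frame affine parameters
#'   `(a, b, c, d, tx, ty)` (identity at 0), residuals before/after, and
#'   divergence flags.
#' @export
stabilize_affine <- function(clip, reference_index = 1L, mask = NULL,
                             max_iters = 50L, pyramid_levels = 3L, tol = 1e-4) {
  stopifnot(inherits(clip, "video_clip"))
  d <- dim(clip$frames)
  T <- d[4]
  if (T < 2L) stop("need at least 2 frames")
  ri <- as.integer(reference_index)
  stopifnot(ri >= 1L, ri <= T)
  gray <- gray_stack(clip$frames)
  ref <- gray[, , ri]
  region <- NULL
  if (!is.null(mask)) {
    check_mask_clip(mask, clip)
    region <- dilate_mask(mask$mask, 5L)
  }
  params <- matrix(0, T, 6L,
                   dimnames = list(NULL, c("a", "b", "c", "d", "tx", "ty")))
  res_before <- res_after <- numeric(T)
  diverged <- logical(T)
  out <- clip$frames
  for (t in seq_len(T)) {
    res_before[t] <- masked_mad(gray[, , t], ref, region)
    if (t == ri) { res_after[t] <- res_before[t]; next }
    p <- estimate_affine(ref, gray[, , t], max_iters = max_iters,
                         levels = pyramid_levels, tol = tol)
    # a near-identity estimate (< 0.25 px displacement anywhere in frame) is
    # not worth warping: sub-quarter-pixel estimates on a pulsing scene are
    # within the photometric bias floor of differential motion estimation
    # (brightness changes masquerade as tiny affine motion), and warping at
    # that scale blurs more than it stabilizes
    px_equiv <- max(abs(p * c(rep(max(d[1:2]) / 2, 4), 1, 1)))
    if (px_equiv < 0.25) {
      params[t, ] <- p
      res_after[t] <- res_before[t]
      next
    }
    warped <- warp_affine_matrix(gray[, , t], p)
    res_after[t] <- masked_mad(warped, ref, region)
    if (res_after[t] > res_before[t] + 1e-12) {
      warning(sprintf("stabilization diverged on frame %d; passing through unwarped", t))
      diverged[t] <- TRUE
      params[t, ] <- 0
      res_after[t] <- res_before[t]
    } else {
      params[t, ] <- p
      out[, , , t] <- warp_affine_frame(clip$frames[, , , t, drop = TRUE], p)
    }
  }
  report <- structure(list(params = params, residual_before = res_before,
                           residual_after = res_after, diverged = diverged,
                           reference_index = ri),
                      class = "stabilization_report")
  list(clip = video_clip(out, clip$fps), report = report)
}

#' @export
print.stabilization_report <- function(x, ...) {
  cat(sprintf("<stabilization_report> %d frames (ref %d), mean residual %.4g -> %.4g, %d diverged\n",
              nrow(x$params), x$reference_index, mean(x$residual_before),
              mean(x$residual_after), sum(x$diverged)))
  invisible(x)
}

# mean of channels -> grayscale stack H x W x T
gray_stack <- function(frames) {
  d <- dim(frames)
  array((frames[, , 1, ] + frames[, , 2, ] + frames[, , 3, ]) / 3,
        c(d[1], d[2], d[4]))
}

masked_mad <- function(a, b, region) {
  if (is.null(region)) mean(abs(a - b)) else mean(abs(a[region] - b[region]))
}

# binary dilation by a (2r+1)-square structuring element
dilate_mask <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2L * r, W + 2L * r)
  pad[r + (1:H), r + (1:W)] <- m
  out <- matrix(FALSE, H, W)
  for (dr in -r:r) for (dc in -r:r) {
    out <- out | pad[r + (1:H) + dr, r + (1:W) + dc]
  }
  out
}

# Gauss-Newton estimation of affine p aligning moving -> ref (ref geometry),
# coarse-to-fine. Returns p such that warp_affine_matrix(moving, p) ~ ref.
estimate_affine <- function(ref, moving, max_iters = 50L, levels = 3L, tol = 1e-4) {
  pyr_ref <- list(ref); pyr_mov <- list(moving)
  for (l in seq_len(levels - 1L)) {
    if (min(dim(pyr_ref[[l]])) < 16L) break
    pyr_ref[[l + 1L]] <- pyr_down(pyr_ref[[l]])
    pyr_mov[[l + 1L]] <- pyr_down(pyr_mov[[l]])
  }
  p <- rep(0, 6)
  for (l in rev(seq_along(pyr_ref))) {
    if (l < length(pyr_ref)) p[5:6] <- p[5:6] * 2   # translations scale up
    p <- refine_affine(pyr_ref[[l]], pyr_mov[[l]], p, max_iters, tol)
  }
  p
}

refine_affine <- function(ref, moving, p, max_iters, tol) {
  H <- nrow(ref); W <- ncol(ref)
  grid <- expand_grid_rc(H, W)
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  xc <- grid$c - cx; yc <- grid$r - cy
  for (it in seq_len(max_iters)) {
    s <- affine_src_coords(p, grid$r, grid$c, H, W)
    Iw <- matrix(bilinear_sample(moving, s$row, s$col), H, W)
    err <- as.vector(ref) - as.vector(Iw)
    g <- grad_rc(Iw)
    gx <- as.vector(g$c); gy <- as.vector(g$r)
    # Jacobian of source coords wrt p = (a,b,c,d,tx,ty)
    J <- cbind(gx * xc, gx * yc, gy * xc, gy * yc, gx, gy)
    JtJ <- crossprod(J)
    rhs <- crossprod(J, err)
    dp <- tryCatch(solve(JtJ + diag(1e-8, 6), rhs), error = function(e) NULL)
    if (is.null(dp)) break
    p <- p + as.vector(dp)
    if (max(abs(dp)) < tol) break
  }
  p
}

#' Suppress slow residual global motion
#'
#' A deliberately simple residual-motion suppressor: the global translation
#' of every frame relative to the temporal mean frame is estimated by
#' differential registration, the resulting 2-D trajectory is low-pass
#' filtered below `cutoff` Hz (ideal frequency-domain filter, DC removed),
#' and each frame is warped by the negative of that slow component. Motion
#' and colour content at frequencies above the cutoff - in particular the
#' 0.8-3 Hz pulsatile analysis band - are untouched: a clip with a pure
#' in-band colour oscillation and no motion passes through with its
#' amplitude preserved, because the estimated trajectory is essentially
#' zero and sub-millipixel warps are skipped.
#'
#' @param clip a [video_clip].
#' @param cutoff low-pass cutoff in Hz, below the analysis band and the
#'   Nyquist frequency (default 0.5).
#' @return A [video_clip] with slow global drift compensated.
#' @export
attenuate_residual_motion <- function(clip, cutoff = 0.5) {
  stopifnot(inherits(clip, "video_clip"))
  if (cutoff >= clip$fps / 2) stop("cutoff must be below the Nyquist frequency")
  d <- dim(clip$frames)
  T <- d[4]
  gray <- gray_stack(clip$frames)
  ref <- apply_temporal_mean(clip$frames)
  refg <- (ref[, , 1] + ref[, , 2] + ref[, , 3]) / 3
  traj <- matrix(0, T, 2L)                          # (col, row) shifts
  for (t in seq_len(T)) {
    traj[t, ] <- estimate_translation(refg, gray[, , t])
  }
  slow <- apply(traj, 2L, lowpass_series, fps = clip$fps, cutoff = cutoff)
  out <- clip$frames
  for (t in seq_len(T)) {
    if (max(abs(slow[t, ])) < 1e-3) next            # skip negligible warps
    p <- c(0, 0, 0, 0, slow[t, 1], slow[t, 2])
    out[, , , t] <- warp_affine_frame(clip$frames[, , , t, drop = TRUE], p)
  }
  video_clip(out, clip$fps)
}

# ideal low-pass below cutoff, DC (mean) removed: the returned component is
# the slow drift to be subtracted from the trajectory by warping
lowpass_series <- function(x, fps, cutoff) {
  T <- length(x)
  F <- stats::fft(x)
  k <- 0:(T - 1)
  f <- pmin(k, T - k) * fps / T
  F[!(f > 0 & f <= cutoff)] <- 0
  Re(stats::fft(F, inverse = TRUE)) / T
}

# translation-only differential registration (2 pyramid levels)
estimate_translation <- function(ref, moving) {
  p <- estimate_translation_level(pyr_down(ref), pyr_down(moving), c(0, 0)) * 2
  estimate_translation_level(ref, moving, p)
}

estimate_translation_level <- function(ref, moving, p, max_iters = 30L) {
  H <- nrow(ref); W <- ncol(ref)
  grid <- expand_grid_rc(H, W)
  for (it in seq_len(max_iters)) {
    Iw <- matrix(bilinear_sample(moving, grid$r + p[2], grid$c + p[1]), H, W)
    err <- as.vector(ref) - as.vector(Iw)
    g <- grad_rc(Iw)
    J <- cbind(as.vector(g$c), as.vector(g$r))
    dp <- tryCatch(solve(crossprod(J) + diag(1e-10, 2), crossprod(J, err)),
                   error = function(e) NULL)
    if (is.null(dp)) break
    p <- p + as.vector(dp)
    if (max(abs(dp)) < 1e-4) break
  }
  p
}
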