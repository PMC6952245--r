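# Shared fixtures, built in code at test time.

# smooth random texture in [lo, hi]: white noise blurred twice (smoothness
# matters so that bilinear warps of the texture are well modelled)
textured_frame <- function(H, W, seed = 7, lo = 0.2, hi = 0.8) {
  set.seed(seed)
  m <- matrix(runif(H * W), H, W)
  k <- matrix(1 / 25, 5, 5)
  pad <- function(x) x[c(1, 1, seq_len(nrow(x)), nrow(x), nrow(x)),
                       c(1, 1, seq_len(ncol(x)), ncol(x), ncol(x))]
  for (i in 1:2) {
    p <- pad(m)
    m <- matrix(0, H, W)
    for (dr in 0:4) for (dc in 0:4)
      m <- m + p[dr + seq_len(H), dc + seq_len(W)] / 25
  }
  lo + (hi - lo) * (m - min(m)) / (max(m) - min(m))
}

# clip whose every frame is the same H x W x 3 array
constant_clip <- function(frame, T, fps) {
  vesselflow::video_clip(array(rep(frame, T), c(dim(frame), T)), fps)
}

# grayscale frame -> RGB
rgb_frame <- function(m) array(rep(m, 3), c(dim(m), 3))

# single-pixel-controlled clip: base intensity plus a per-frame scalar
# series added to one pixel of one channel
oscillating_pixel_clip <- function(series, H = 8, W = 8, fps = 30,
                                   base = 0.5, px = c(4, 4), channel = 2) {
  T <- length(series)
  a <- array(base, c(H, W, 3, T))
  a[px[1], px[2], channel, ] <- base + series
  vesselflow::video_clip(a, fps)
}

# straight horizontal tube mask in an H x W frame
bar_mask <- function(H = 40, W = 100, row = 20, halfwidth = 2,
                     col_from = 6, col_to = 95) {
  m <- matrix(FALSE, H, W)
  m[(row - halfwidth):(row + halfwidth), col_from:col_to] <- TRUE
  vesselflow::vessel_mask(m)
}
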