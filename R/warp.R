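# Internal geometry helpers shared by stabilize, synth and annotate.
# All warping uses bilinear interpolation with edge replication so no dark
# borders leak into vertex means.

# Sample a matrix at (possibly fractional) coordinates with bilinear
# interpolation; coordinates outside the image are clamped to the edge.
bilinear_sample <- function(img, r, c) {
  H <- nrow(img); W <- ncol(img)
  r <- pmin(pmax(r, 1), H)
  c <- pmin(pmax(c, 1), W)
  r0 <- floor(r); c0 <- floor(c)
  r0 <- pmin(r0, H - 1L); c0 <- pmin(c0, W - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- r0 + (c0 - 1) * H
  i10 <- i00 + 1
  i01 <- i00 + H
  i11 <- i01 + 1
  (1 - fr) * (1 - fc) * img[i00] + fr * (1 - fc) * img[i10] +
    (1 - fr) * fc * img[i01] + fr * fc * img[i11]
}

# Affine parameter vector p = (a, b, c, d, tx, ty), identity at 0, mapping
# centered reference coords (xc = col - cx, yc = row - cy) to source coords:
#   col_src = cx + (1+a) xc + b yc + tx
#   row_src = cy + c xc + (1+d) yc + ty
affine_src_coords <- function(p, rows, cols, H, W) {
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  xc <- cols - cx; yc <- rows - cy
  list(col = cx + (1 + p[1]) * xc + p[2] * yc + p[5],
       row = cy + p[3] * xc + (1 + p[4]) * yc + p[6])
}

# Warp a single-channel image so that output(ref coords) = input(affine(p)).
warp_affine_matrix <- function(img, p) {
  H <- nrow(img); W <- ncol(img)
  grid <- expand_grid_rc(H, W)
  s <- affine_src_coords(p, grid$r, grid$c, H, W)
  matrix(bilinear_sample(img, s$row, s$col), H, W)
}

# Warp every channel of an H x W x 3 frame.
warp_affine_frame <- function(frame, p) {
  out <- frame
  for (ch in seq_len(dim(frame)[3])) out[, , ch] <- warp_affine_matrix(frame[, , ch], p)
  out
}

# row/col index vectors for all pixels, column-major (R storage order)
expand_grid_rc <- function(H, W) {
  list(r = rep.int(seq_len(H), W), c = rep(seq_len(W), each = H))
}

# 2x downsampling by 2x2 block average (odd trailing row/col dropped)
pyr_down <- function(img) {
  H <- nrow(img) %/% 2L; W <- ncol(img) %/% 2L
  if (H < 1L || W < 1L) return(img)
  a <- img[seq_len(2L * H), seq_len(2L * W), drop = FALSE]
  0.25 * (a[seq(1, 2 * H, 2), seq(1, 2 * W, 2), drop = FALSE] +
          a[seq(2, 2 * H, 2), seq(1, 2 * W, 2), drop = FALSE] +
          a[seq(1, 2 * H, 2), seq(2, 2 * W, 2), drop = FALSE] +
          a[seq(2, 2 * H, 2), seq(2, 2 * W, 2), drop = FALSE])
}

# central-difference spatial gradients (edge rows/cols use one-sided)
grad_rc <- function(img) {
  H <- nrow(img); W <- ncol(img)
  gr <- img; gc <- img
  gr[2:(H - 1), ] <- (img[3:H, ] - img[1:(H - 2), ]) / 2
  gr[1, ] <- img[2, ] - img[1, ]; gr[H, ] <- img[H, ] - img[H - 1, ]
  gc[, 2:(W - 1)] <- (img[, 3:W] - img[, 1:(W - 2)]) / 2
  gc[, 1] <- img[, 2] - img[, 1]; gc[, W] <- img[, W] - img[, W - 1]
  list(r = gr, c = gc)
}
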