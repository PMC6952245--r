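#' Overlay flow-direction arrows on a representative frame
#'
#' Draws one arrow per accepted vertex pair, spanning the pair's polyline
#' vertices, with the tail at the higher-phase vertex and the head at the
#' lower-phase vertex (phase decreases along the flow). Rejected pairs leave
#' gaps, so unreliable stretches of vessel are visibly unannotated. With no
#' accepted pairs the frame is returned unchanged except for an
#' "INDETERMINATE" caption in the top-left corner. Rendering is a pure
#' function of its inputs.
#'
#' @param frame `H x W x 3` colour image in \[0, 1\] (typically the
#'   stabilization reference frame).
#' @param result a `flow_direction` from [infer_direction()].
#' @param polyline the `centerline_polyline` the result refers to.
#' @param colour arrow colour (any R colour; default `"cyan"`, chosen for
#'   contrast against tissue).
#' @param width arrow line width in px.
#' @return Object of class `annotated_frame`: list with `image`,
#'   `arrow_segments` (data frame of tail/head coordinates) and `colour`.
#' @export
render_arrows <- function(frame, result, polyline, colour = "cyan", width = 2) {
  stopifnot(inherits(result, "flow_direction"))
  img <- frame
  rgb <- as.vector(grDevices::col2rgb(colour)) / 255
  acc <- result$pairs[result$pairs$status == "accepted", , drop = FALSE]
  segs <- data.frame(from_row = numeric(0), from_col = numeric(0),
                     to_row = numeric(0), to_col = numeric(0))
  if (nrow(acc) == 0L) {
    img <- draw_text(img, "INDETERMINATE", at = c(3, 3), rgb = rgb)
    return(structure(list(image = img, arrow_segments = segs, colour = colour),
                     class = "annotated_frame"))
  }
  for (i in seq_len(nrow(acc))) {
    p <- acc[i, ]
    if (p$direction == "forward") {
      from <- c(p$row_a, p$col_a); to <- c(p$row_b, p$col_b)
    } else {
      from <- c(p$row_b, p$col_b); to <- c(p$row_a, p$col_a)
    }
    img <- draw_arrow(img, from, to, rgb, width)
    segs <- rbind(segs, data.frame(from_row = from[1], from_col = from[2],
                                   to_row = to[1], to_col = to[2]))
  }
  structure(list(image = img, arrow_segments = segs, colour = colour),
            class = "annotated_frame")
}

#' @export
print.annotated_frame <- function(x, ...) {
  cat(sprintf("<annotated_frame> %d x %d px, %d arrows (%s)\n",
              dim(x$image)[1], dim(x$image)[2], nrow(x$arrow_segments), x$colour))
  invisible(x)
}

#' Phase colourmap over the vessel region
#'
#' Colours every mask pixel by the heart-rate-frequency phase of its nearest
#' sampled vertex, using a perceptually ordered colourmap (viridis) over the
#' fixed range `[-pi, pi]` so that colours are comparable across videos.
#' Background pixels are left untouched.
#'
#' @param frame `H x W x 3` base image in \[0, 1\].
#' @param mask a [vessel_mask].
#' @param profile a `phase_profile`.
#' @return `H x W x 3` image with the vessel region coloured by phase.
#' @export
render_phase_map <- function(frame, mask, profile) {
  stopifnot(inherits(mask, "vessel_mask"), inherits(profile, "phase_profile"))
  img <- frame
  pal <- grDevices::col2rgb(grDevices::hcl.colors(256, "viridis")) / 255
  px <- which(mask$mask, arr.ind = TRUE)
  d2 <- outer(px[, 1], profile$vertices[, 1], "-")^2 +
        outer(px[, 2], profile$vertices[, 2], "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  theta <- profile$theta[nearest]
  ci <- pmin(256L, 1L + as.integer(floor((theta + pi) / (2 * pi) * 256)))
  H <- nrow(mask$mask)
  lin <- px[, 1] + (px[, 2] - 1L) * H
  HW <- H * ncol(mask$mask)
  for (ch in 1:3) img[lin + (ch - 1L) * HW] <- pal[ch, ci]
  img
}

# --- raster drawing primitives -------------------------------------------

# paint a disk-brushed segment between two (row, col) points
draw_segment <- function(img, from, to, rgb, width) {
  len <- sqrt(sum((to - from)^2))
  n <- max(2L, ceiling(len / 0.4))
  u <- seq(0, 1, length.out = n)
  pr <- from[1] + u * (to[1] - from[1])
  pc <- from[2] + u * (to[2] - from[2])
  rad <- max(0.5, width / 2)
  ir <- -ceiling(rad):ceiling(rad)
  offs <- expand.grid(dr = ir, dc = ir)
  offs <- offs[offs$dr^2 + offs$dc^2 <= rad^2 + 0.26, , drop = FALSE]
  H <- dim(img)[1]; W <- dim(img)[2]
  rr <- round(rep(pr, each = nrow(offs)) + offs$dr)
  cc <- round(rep(pc, each = nrow(offs)) + offs$dc)
  keep <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
  lin <- unique(rr[keep] + (cc[keep] - 1L) * H)
  for (ch in 1:3) img[lin + (ch - 1L) * H * W] <- rgb[ch]
  img
}

# segment plus a two-barb arrowhead at `to`
draw_arrow <- function(img, from, to, rgb, width) {
  img <- draw_segment(img, from, to, rgb, width)
  v <- to - from
  len <- sqrt(sum(v^2))
  if (len < 1e-9) return(img)
  d <- v / len
  bl <- min(6, 0.4 * len)                   # barb length
  for (ang in c(150, -150) * pi / 180) {
    bd <- c(cos(ang) * d[1] - sin(ang) * d[2],
            sin(ang) * d[1] + cos(ang) * d[2])
    img <- draw_segment(img, to, to + bl * bd, rgb, width)
  }
  img
}

# minimal 3x5 bitmap font (letters needed for captions)
caption_font <- function() {
  list(
    I = c("111", "010", "010", "010", "111"),
    N = c("101", "111", "111", "111", "101"),
    D = c("110", "101", "101", "101", "110"),
    E = c("111", "100", "111", "100", "111"),
    T = c("111", "010", "010", "010", "010"),
    R = c("110", "101", "110", "101", "101"),
    M = c("101", "111", "111", "101", "101"),
    A = c("010", "101", "111", "101", "101")
  )
}

# stamp text at (row, col) top-left, 3x5 glyphs with 1 px spacing
draw_text <- function(img, text, at, rgb) {
  font <- caption_font()
  H <- dim(img)[1]; W <- dim(img)[2]
  col0 <- at[2]
  for (ch_ in strsplit(text, "")[[1]]) {
    glyph <- font[[ch_]]
    if (!is.null(glyph)) {
      for (gr in 1:5) {
        bits <- strsplit(glyph[gr], "")[[1]] == "1"
        for (gc in 1:3) {
          if (!bits[gc]) next
          r <- at[1] + gr - 1L; c <- col0 + gc - 1L
          if (r >= 1 && r <= H && c >= 1 && c <= W) {
            img[r, c, ] <- rgb
          }
        }
      }
    }
    col0 <- col0 + 4L
  }
  img
}

#' Write an image array to PNG
#'
#' @param img `H x W x 3` array in \[0, 1\] (or an `annotated_frame`).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(img, path) {
  if (inherits(img, "annotated_frame")) img <- img$image
  png::writePNG(img, target = path)
  invisible(path)
}
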