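#' Construct a video clip
#'
#' A `video_clip` is the package's in-memory representation of a short colour
#' video: a numeric array of dimension `H x W x 3 x T` with intensities in
#' \[0, 1\] and a frame rate in Hz. The channel order is fixed as red, green,
#' blue (the green channel, index 2, carries the photoplethysmographic signal
#' analysed downstream). Pixel coordinates throughout the package are 1-based
#' `(row, col)` with row 1 at the top of the frame.
#'
#' @param frames numeric array `H x W x 3 x T` (or `H x W x T` for grayscale,
#'   which is replicated across the three channels), intensities in \[0, 1\].
#' @param fps frame rate in Hz (> 0).
#' @return An object of class `video_clip`: a list with elements `frames` and
#'   `fps`.
#' @examples
#' clip <- video_clip(array(0.5, c(8, 10, 3, 4)), fps = 30)
#' clip_duration(clip) # 4/30 s
#' @export
video_clip <- function(frames, fps) {
  if (length(dim(frames)) == 3L) {
    d <- dim(frames)
    frames <- array(rep(frames, each = 1L), c(d[1], d[2], 1L, d[3]))[, , c(1, 1, 1), , drop = FALSE]
  }
  stopifnot(length(dim(frames)) == 4L, dim(frames)[3] == 3L)
  d <- dim(frames)
  if (d[4] < 2L) stop("a video clip needs at least 2 frames")
  if (d[1] < 1L || d[2] < 1L) stop("frames must have positive height and width")
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("fps must be a single positive number")
  if (anyNA(frames) || !all(is.finite(frames))) stop("frame intensities must be finite")
  rng <- range(frames)
  if (rng[1] < 0 || rng[2] > 1) stop("frame intensities must lie in [0, 1]")
  structure(list(frames = frames, fps = as.numeric(fps)), class = "video_clip")
}

#' @rdname video_clip
#' @param clip a `video_clip`.
#' @export
clip_duration <- function(clip) {
  dim(clip$frames)[4] / clip$fps
}

#' @export
print.video_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<video_clip> %d x %d px, %d frames @ %g fps (%.2f s)\n",
              d[1], d[2], d[4], x$fps, clip_duration(x)))
  invisible(x)
}

#' Construct a vessel mask
#'
#' Binary labelmap of the segmented vessel, drawn on a reference frame of the
#' clip it accompanies (the polygon segmentation of the vessel under
#' investigation). Any nonzero pixel is foreground.
#'
#' @param mask numeric or logical matrix `H x W`; nonzero means vessel.
#' @param frame_index 1-based index of the frame the mask was drawn on.
#' @return An object of class `vessel_mask`: list with `mask` (logical matrix)
#'   and `frame_index`.
#' @export
vessel_mask <- function(mask, frame_index = 1L) {
  stopifnot(is.matrix(mask))
  m <- mask != 0
  if (!any(m)) stop("empty mask: no foreground pixels")
  structure(list(mask = m, frame_index = as.integer(frame_index)),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %d x %d px, %d foreground pixels (frame %d)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$frame_index))
  invisible(x)
}

# internal: check mask/clip dimension agreement
check_mask_clip <- function(mask, clip) {
  d <- dim(clip$frames)
  if (nrow(mask$mask) != d[1] || ncol(mask$mask) != d[2])
    stop(sprintf("mask dimensions (%d x %d) do not match clip frames (%d x %d)",
                 nrow(mask$mask), ncol(mask$mask), d[1], d[2]))
  invisible(TRUE)
}
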