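#' Read a video clip from a directory of numbered frames
#'
#' Reads a lossless frame stack: a directory of PNG or TIFF images named so
#' that lexicographic order is frame order (e.g. `frame_00001.png`). 8-bit
#' input is rescaled so that 255 maps exactly to 1.0. All frames must share
#' the same dimensions; grayscale frames are replicated to RGB and any alpha
#' channel is dropped.
#'
#' @param path directory containing the frames.
#' @param fps_override frame rate in Hz; required for frame directories (the
#'   stack itself carries no timing metadata).
#' @return A [video_clip].
#' @seealso [write_clip()] for the lossless inverse.
#' @export
read_clip <- function(path, fps_override = NULL) {
  if (!dir.exists(path)) stop("unreadable path: ", path)
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                      full.names = TRUE)
  files <- sort(files)
  if (length(files) == 0L) stop("no frames found in ", path)
  if (is.null(fps_override)) stop("fps_override is required for frame directories")
  frames <- lapply(files, read_frame)
  d1 <- dim(frames[[1]])
  same <- vapply(frames, function(f) identical(dim(f), d1), logical(1))
  if (!all(same)) stop("inconsistent frame sizes in ", path)
  arr <- array(unlist(frames, use.names = FALSE), c(d1, length(frames)))
  video_clip(arr, fps = fps_override)
}

# internal: read one image file as an H x W x 3 array in [0,1]
read_frame <- function(file) {
  img <- if (grepl("\\.png$", file, ignore.case = TRUE)) {
    png::readPNG(file)
  } else {
    tiff::readTIFF(file)
  }
  to_rgb_array(img)
}

# internal: normalise grayscale/RGBA image arrays to H x W x 3
to_rgb_array <- function(img) {
  if (is.matrix(img)) {
    array(img, c(dim(img), 3L))
  } else if (length(dim(img)) == 3L && dim(img)[3] >= 3L) {
    img[, , 1:3, drop = FALSE]
  } else if (length(dim(img)) == 3L && dim(img)[3] == 1L) {
    array(img[, , 1], c(dim(img)[1:2], 3L))
  } else {
    stop("unsupported image layout")
  }
}

#' Write a video clip as a lossless PNG frame stack
#'
#' Writes `frame_00001.png`, `frame_00002.png`, ... into `path`. Output is
#' 8-bit PNG; intensities already on the 8-bit lattice (multiples of 1/255)
#' round-trip exactly through [read_clip()].
#'
#' @param clip a [video_clip].
#' @param path output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_clip <- function(clip, path) {
  stopifnot(inherits(clip, "video_clip"))
  d <- dim(clip$frames)
  if (d[4] < 1L) stop("clip has no frames")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("unwritable path: ", path)
  files <- file.path(path, sprintf("frame_%05d.png", seq_len(d[4])))
  for (t in seq_len(d[4])) {
    png::writePNG(clip$frames[, , , t], target = files[t])
  }
  invisible(files)
}

#' Read a vessel segmentation mask
#'
#' Reads a single-channel (or RGB, first channel used) PNG/TIFF labelmap and
#' binarises it: any nonzero pixel becomes foreground. Dimensions must match
#' the clip the mask accompanies.
#'
#' @param path mask image file.
#' @param clip the [video_clip] the mask belongs to.
#' @param frame_index 1-based frame the segmentation was drawn on.
#' @return A [vessel_mask].
#' @export
read_mask <- function(path, clip, frame_index = 1L) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  m <- if (is.matrix(img)) img else img[, , 1]
  mask <- vessel_mask(m, frame_index = frame_index)
  check_mask_clip(mask, clip)
  mask
}

#' Write a vessel mask as a PNG labelmap
#'
#' @param mask a [vessel_mask].
#' @param path output PNG file.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "vessel_mask"))
  png::writePNG(mask$mask * 1, target = path)
  invisible(path)
}
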