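#' Skeletonize a vessel mask
#'
#' Reduces the binary labelmap to a 1-pixel-wide structural skeleton by
#' iterative morphological thinning (Zhang-Suen). The skeleton is a subset of
#' the mask and preserves its topology: a tube thins to a simple 8-connected
#' path, an annulus to a closed loop.
#'
#' @param mask a [vessel_mask] or a logical/numeric matrix.
#' @return Logical matrix of skeleton pixels (class `skeleton`).
#' @export
skeletonize <- function(mask) {
  m <- if (inherits(mask, "vessel_mask")) mask$mask else mask != 0
  if (!any(m)) stop("empty mask: nothing to skeletonize")
  sk <- remove_redundant_pixels(thin_zhang_suen(m))
  if (!any(sk)) stop("mask eroded to nothing during thinning")
  structure(sk, class = c("skeleton", "matrix"))
}

# Sequentially delete pixels whose removal keeps their 3x3 neighbourhood a
# single 8-connected component (and which are not endpoints). Zhang-Suen
# leaves such redundant pixels at diagonal staircases and kinks; removing
# them yields a minimal skeleton where simple paths have vertex degree <= 2.
# A straight-path pixel's two neighbours are non-adjacent (2 components), so
# genuine path pixels are never deleted.
remove_redundant_pixels <- function(m) {
  offs <- neighbour_offsets()
  repeat {
    nc <- neighbour_counts(m)
    cand <- which(m & nc >= 2)
    deleted <- FALSE
    for (i in cand) {
      r <- (i - 1L) %% nrow(m) + 1L; c <- (i - 1L) %/% nrow(m) + 1L
      if (!m[r, c]) next
      nb <- offs + rep(c(r, c), each = 8L)
      keep <- nb[, 1] >= 1 & nb[, 1] <= nrow(m) & nb[, 2] >= 1 & nb[, 2] <= ncol(m)
      nb <- nb[keep, , drop = FALSE]
      nb <- nb[m[nb], , drop = FALSE]
      if (nrow(nb) < 2L) next
      if (n_components8(nb) == 1L) { m[r, c] <- FALSE; deleted <- TRUE }
    }
    if (!deleted) break
  }
  m
}

# number of 8-connected components among a small set of pixel coordinates
n_components8 <- function(px) {
  n <- nrow(px)
  comp <- seq_len(n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (max(abs(px[i, ] - px[j, ])) <= 1L) {
      old <- comp[j]; comp[comp == old] <- comp[i]
    }
  }
  length(unique(comp))
}

# Zhang-Suen thinning, vectorized over the whole image. Neighbours of P1 are
# labelled clockwise from north: P2=N, P3=NE, P4=E, P5=SE, P6=S, P7=SW, P8=W,
# P9=NW. A pixel is deleted when it has 2..6 foreground neighbours, exactly
# one 0->1 transition around the ring, and the sub-iteration's corner
# conditions hold.
thin_zhang_suen <- function(m) {
  img <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
  img[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- as.integer(m)
  H <- nrow(img); W <- ncol(img)
  sh <- function(x, dr, dc) { # shifted copy: value of neighbour at offset
    out <- matrix(0L, H, W)
    rs <- max(1, 1 + dr):min(H, H + dr); cs <- max(1, 1 + dc):min(W, W + dc)
    out[rs - dr, cs - dc] <- x[rs, cs]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- sh(img, -1, 0); p3 <- sh(img, -1, 1); p4 <- sh(img, 0, 1)
      p5 <- sh(img, 1, 1);  p6 <- sh(img, 1, 0);  p7 <- sh(img, 1, -1)
      p8 <- sh(img, 0, -1); p9 <- sh(img, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cond <- img == 1L & b >= 2 & b <= 6 & a == 1
      if (step == 1L) {
        cond <- cond & (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- cond & (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) { img[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  img[2:(H - 1L), 2:(W - 1L)] == 1L
}

# count of foreground 8-neighbours for every pixel of a logical matrix
neighbour_counts <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- as.integer(m)
  n <- matrix(0L, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    n <- n + pad[(2:(H + 1L)) + dr, (2:(W + 1L)) + dc]
  }
  n
}

#' Prune short skeleton spurs
#'
#' Thinning of hand-drawn polygon masks produces short side branches (spurs)
#' at boundary irregularities. Branches shorter than `min_px` pixels that end
#' in a free endpoint and attach to a junction are removed, repeatedly, until
#' stable. Designed to restore the simple-path topology the tracing step
#' assumes.
#'
#' @param skel skeleton matrix from [skeletonize()].
#' @param min_px branches strictly shorter than this are removed (default 10).
#' @return Pruned skeleton matrix.
#' @export
prune_spurs <- function(skel, min_px = 10L) {
  m <- unclass(skel) == 1 | unclass(skel) == TRUE
  offs <- neighbour_offsets()
  repeat {
    nc <- neighbour_counts(m)
    if (!any(m & nc >= 3)) break     # no junctions, nothing to prune
    ends <- which(m & nc == 1, arr.ind = TRUE)
    if (nrow(ends) == 0L) break
    removed_any <- FALSE
    for (i in seq_len(nrow(ends))) {
      branch <- walk_branch(m, ends[i, 1], ends[i, 2], offs, max_len = min_px)
      if (!is.null(branch) && nrow(branch) < min_px) {
        m[branch] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
    # branch removal can leave a redundant attachment pixel at the junction
    m <- remove_redundant_pixels(thin_zhang_suen(m))
  }
  structure(m, class = c("skeleton", "matrix"))
}

# follow a branch from an endpoint until a junction (>=3 neighbours) or
# max_len steps; returns the branch pixels (junction excluded) or NULL if no
# junction was reached within max_len (i.e. the branch is the main path)
walk_branch <- function(m, r, c, offs, max_len) {
  nc <- neighbour_counts(m)
  path <- matrix(NA_integer_, 0L, 2L)
  visited <- matrix(FALSE, nrow(m), ncol(m))
  repeat {
    if (nrow(path) >= max_len) return(NULL)
    path <- rbind(path, c(r, c)); visited[r, c] <- TRUE
    nxt <- NULL
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
      if (rr < 1 || cc < 1 || rr > nrow(m) || cc > ncol(m)) next
      if (m[rr, cc] && !visited[rr, cc]) {
        if (nc[rr, cc] >= 3) return(path)   # reached the junction
        nxt <- c(rr, cc); break
      }
    }
    if (is.null(nxt)) return(NULL)          # free end: this IS the main path
    r <- nxt[1]; c <- nxt[2]
  }
}

# clockwise neighbour order starting from north (deterministic tie-break)
neighbour_offsets <- function() {
  matrix(c(-1L, 0L,  -1L, 1L,  0L, 1L,  1L, 1L,
            1L, 0L,   1L, -1L, 0L, -1L, -1L, -1L),
         ncol = 2L, byrow = TRUE)
}

#' Trace a skeleton into an ordered pixel path
#'
#' Converts the 1-px skeleton to an ordered list of pixel coordinates by a
#' two-pass traversal: starting from the first foreground pixel in
#' column-major scan order (or a supplied start pixel), repeatedly step to an
#' unvisited 8-connected skeleton neighbour until a free end is reached; then
#' clear the record and repeat from that end, which guarantees a complete
#' end-to-end traversal of a simple-path skeleton regardless of where the
#' scan started. At junction pixels (3 or more skeleton neighbours) the next
#' pixel is chosen in fixed clockwise order starting from north, and a
#' warning is emitted.
#'
#' @param skel skeleton matrix.
#' @param start optional `(row, col)` start pixel; default is the first
#'   nonzero pixel in column-major order.
#' @return Integer matrix `L x 2` of `(row, col)` path pixels in traversal
#'   order.
#' @export
trace_skeleton <- function(skel, start = NULL) {
  m <- unclass(skel) == 1 | unclass(skel) == TRUE
  if (!any(m)) stop("empty skeleton")
  if (is.null(start)) {
    i <- which(m)[1]                       # column-major first nonzero
    start <- c((i - 1L) %% nrow(m) + 1L, (i - 1L) %/% nrow(m) + 1L)
  } else {
    start <- as.integer(start)
    if (!m[start[1], start[2]]) stop("start pixel is not on the skeleton")
  }
  if (any(neighbour_counts(m)[m] >= 3))
    warning("skeleton has junctions; traversal uses deterministic neighbour order")
  p1 <- walk_path(m, start)
  end1 <- p1[nrow(p1), ]
  walk_path(m, end1)
}

# greedy walk from a start pixel over unvisited skeleton neighbours
walk_path <- function(m, start) {
  offs <- neighbour_offsets()
  visited <- matrix(FALSE, nrow(m), ncol(m))
  path <- matrix(NA_integer_, sum(m), 2L)
  n <- 0L; r <- start[1]; c <- start[2]
  repeat {
    n <- n + 1L; path[n, ] <- c(r, c); visited[r, c] <- TRUE
    nxt <- NULL
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
      if (rr < 1 || cc < 1 || rr > nrow(m) || cc > ncol(m)) next
      if (m[rr, cc] && !visited[rr, cc]) { nxt <- c(rr, cc); break }
    }
    if (is.null(nxt)) break
    r <- nxt[1]; c <- nxt[2]
  }
  path[seq_len(n), , drop = FALSE]
}

#' Downsample a traced path into a centerline polyline
#'
#' Keeps every `k`-th path pixel starting from the first, and always the last
#' pixel, giving `ceiling((L-1)/k) + 1` vertices for a path of length `L`.
#' The default factor of 25 gives a vertex spacing coarse enough that
#' adjacent-vertex pulse-wave delays are measurable; spacing is reported in
#' pixels (convert to mm only if pixel size is known).
#'
#' @param path `L x 2` integer matrix from [trace_skeleton()].
#' @param k positive integer downsampling factor (default 25).
#' @return Object of class `centerline_polyline`: list with `vertices`
#'   (`V x 2` matrix of `(row, col)`), `downsample_factor`,
#'   `source_path_length`.
#' @export
downsample_polyline <- function(path, k = 25L) {
  stopifnot(is.matrix(path), ncol(path) == 2L)
  L <- nrow(path)
  if (L < 2L) stop("path must contain at least 2 pixels")
  k <- as.integer(k)
  if (k < 1L) stop("downsampling factor must be >= 1")
  if (k >= L) warning("downsampling factor >= path length; polyline degenerates to the endpoints")
  idx <- unique(c(seq(1L, L, by = k), L))
  structure(list(vertices = path[idx, , drop = FALSE],
                 vertex_index = idx,
                 downsample_factor = k,
                 source_path_length = L),
            class = "centerline_polyline")
}

#' @export
print.centerline_polyline <- function(x, ...) {
  cat(sprintf("<centerline_polyline> %d vertices (factor %d from %d skeleton px)\n",
              nrow(x$vertices), x$downsample_factor, x$source_path_length))
  invisible(x)
}

#' Extract a centerline polyline from a vessel mask
#'
#' Convenience wrapper running [skeletonize()], [prune_spurs()],
#' [trace_skeleton()] and [downsample_polyline()] in sequence.
#'
#' @param mask a [vessel_mask].
#' @param k downsampling factor (default 25).
#' @param auto if `TRUE`, choose the largest factor `<= k` that yields at
#'   least 5 vertices (falls back to the full path when the vessel is short).
#' @param prune_spurs_px remove skeleton spurs shorter than this many pixels
#'   before tracing (0 disables; default 10).
#' @return A `centerline_polyline`.
#' @export
extract_centerline <- function(mask, k = 25L, auto = FALSE, prune_spurs_px = 10L) {
  sk <- skeletonize(mask)
  if (prune_spurs_px > 0L) sk <- prune_spurs(sk, min_px = prune_spurs_px)
  path <- trace_skeleton(sk)
  L <- nrow(path)
  if (auto) {
    kk <- as.integer(k)
    while (kk > 1L && ceiling((L - 1) / kk) + 1 < 5) kk <- kk - 1L
    k <- kk
  }
  downsample_polyline(path, k)
}
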