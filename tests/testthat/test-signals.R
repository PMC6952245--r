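# minimal polyline constructor for hand-built fixtures
make_polyline <- function(vertices) {
  structure(list(vertices = vertices,
                 vertex_index = seq_len(nrow(vertices)),
                 downsample_factor = 1L,
                 source_path_length = nrow(vertices)),
            class = "centerline_polyline")
}

test_that("uniform frames give constant vertex signals", {
  clip <- constant_clip(rgb_frame(matrix(0.7, 20, 30)), T = 10, fps = 30)
  mk <- bar_mask(H = 20, W = 30, row = 10, halfwidth = 2, col_from = 4, col_to = 27)
  pl <- make_polyline(cbind(c(10, 10, 10), c(5, 15, 25)))
  vss <- extract_vertex_signals(clip, mk, pl)
  expect_true(all(abs(vss$signals - 0.7) < 1e-12))
  expect_equal(sum(vss$vertex_pixel_counts), sum(mk$mask))
})

test_that("two separated blobs average to their own means", {
  H <- 20; W <- 40
  m <- matrix(FALSE, H, W)
  m[8:12, 3:10] <- TRUE                      # blob A around (10, 6)
  m[8:12, 30:37] <- TRUE                     # blob B around (10, 33)
  frame <- rgb_frame(matrix(0, H, W))
  frame[, , 2][m] <- 0                        # set below
  g <- matrix(0, H, W); g[8:12, 3:10] <- 0.2; g[8:12, 30:37] <- 0.9
  frame[, , 2] <- g
  clip <- constant_clip(frame, T = 6, fps = 30)
  pl <- make_polyline(cbind(c(10, 10), c(6, 33)))
  vss <- extract_vertex_signals(clip, vessel_mask(m), pl)
  expect_equal(vss$signals[1, ], rep(0.2, 6))
  expect_equal(vss$signals[2, ], rep(0.9, 6))
})

test_that("pixel partition matches a brute-force nearest-vertex scan", {
  set.seed(21)
  H <- 25; W <- 35
  m <- matrix(runif(H * W) < 0.3, H, W)
  m[13, 18] <- TRUE
  verts <- cbind(sample(1:H, 5), sample(1:W, 5))
  pl <- make_polyline(verts)
  clip <- constant_clip(rgb_frame(matrix(0.5, H, W)), T = 4, fps = 30)
  vss <- suppressWarnings(extract_vertex_signals(clip, vessel_mask(m), pl))
  px <- which(m, arr.ind = TRUE)
  brute <- integer(nrow(px))
  for (i in seq_len(nrow(px))) {
    d2 <- (px[i, 1] - verts[, 1])^2 + (px[i, 2] - verts[, 2])^2
    brute[i] <- which(d2 == min(d2))[1]      # ties to the lower vertex index
  }
  expect_identical(vss$assignment, brute)
  expect_equal(vss$vertex_pixel_counts, tabulate(brute, 5))
})

test_that("heart rate locks onto an exact-bin sinusoid", {
  fps <- 30; T <- 300
  t <- (0:(T - 1)) / fps
  sig <- 0.5 + 0.01 * sin(2 * pi * 1.2 * t)
  vss <- structure(list(signals = rbind(sig, sig), fps = fps,
                        vertex_pixel_counts = c(5L, 5L),
                        vertices = cbind(c(1, 2), c(1, 2))),
                   class = "vertex_signals")
  hr <- estimate_heart_rate(vss, band = c(0.8, 3))
  expect_equal(hr$f_heart, 1.2)
  expect_equal(hr$heart_bin, 12L)
})

test_that("the pump waveform's fundamental dominates the band", {
  fps <- 60; T <- 600                         # 10 s at the phantom frame rate
  t <- (0:(T - 1)) / fps
  sig <- 0.5 - 0.05 * pump_waveform(t, period = 1, on_fraction = 1 / 3)
  vss <- structure(list(signals = matrix(sig, 1), fps = fps,
                        vertex_pixel_counts = 10L, vertices = cbind(1, 1)),
                   class = "vertex_signals")
  hr <- estimate_heart_rate(vss, band = c(0.8, 3))
  expect_equal(hr$f_heart, 1.0)
  # brute-force spectrum oracle: fundamental magnitude exceeds in-band harmonics
  mags <- vapply(1:30, function(k) {
    Mod(sum(sig * exp(-2i * pi * k * (0:(T - 1)) / T)))
  }, numeric(1))
  in_band <- which((1:30) * fps / T >= 0.8 & (1:30) * fps / T <= 3)
  expect_equal(in_band[which.max(mags[in_band])] * fps / T, 1.0)
})

test_that("heart-rate estimation is invariant to amplitude and offset", {
  fps <- 60; T <- 480
  t <- (0:(T - 1)) / fps
  base <- pump_waveform(t, 1, 1 / 3, 0.05)
  for (tf in list(c(1, 0), c(0.3, 0.2), c(5, -1))) {
    sig <- tf[1] * base + tf[2]
    vss <- structure(list(signals = matrix(sig, 1), fps = fps,
                          vertex_pixel_counts = 1L, vertices = cbind(1, 1)),
                     class = "vertex_signals")
    expect_equal(estimate_heart_rate(vss, c(0.8, 3))$f_heart, 1.0)
  }
})

test_that("constant signals produce the no-in-band-component error", {
  vss <- structure(list(signals = matrix(0.5, 2, 200), fps = 30,
                        vertex_pixel_counts = c(1L, 1L),
                        vertices = cbind(c(1, 2), c(1, 2))),
                   class = "vertex_signals")
  expect_error(estimate_heart_rate(vss, c(0.8, 3)), "no in-band component")
  # clip so short no bin falls in the band
  vss2 <- structure(list(signals = matrix(rnorm(8), 1), fps = 30,
                         vertex_pixel_counts = 1L, vertices = cbind(1, 1)),
                    class = "vertex_signals")
  expect_error(estimate_heart_rate(vss2, c(0.8, 3)), "no in-band")
})

test_that("phase follows the delay convention theta = -2 pi f dt", {
  fps <- 30; T <- 300; f <- 1               # bin 10
  t <- (0:(T - 1)) / fps
  sig0 <- cos(2 * pi * f * t)
  sig_delayed <- cos(2 * pi * f * (t - 0.25))
  vss <- structure(list(signals = rbind(sig0, sig_delayed, sig0), fps = fps,
                        vertex_pixel_counts = c(1L, 1L, 1L),
                        vertices = cbind(c(1, 2, 3), c(1, 2, 3))),
                   class = "vertex_signals")
  pr <- vertex_phase(vss, heart_bin = 10L, stride = 1L)
  expect_equal(pr$theta[1], 0, tolerance = 1e-6)
  expect_equal(pr$theta[2], -pi / 2, tolerance = 1e-6)
  expect_equal(pr$theta[3] - pr$theta[1], 0, tolerance = 1e-12)
  expect_true(all(pr$theta >= -pi & pr$theta <= pi))
})

test_that("phase is invariant to offset and positive scaling", {
  fps <- 30; T <- 240
  t <- (0:(T - 1)) / fps
  sig <- cos(2 * pi * 1.25 * t - 0.7)        # bin 10
  for (tf in list(c(1, 0), c(4, 0.3), c(0.1, -2))) {
    vss <- structure(list(signals = matrix(tf[1] * sig + tf[2], 1), fps = fps,
                          vertex_pixel_counts = 1L, vertices = cbind(1, 1)),
                     class = "vertex_signals")
    pr <- vertex_phase(vss, heart_bin = 10L, stride = 1L)
    expect_equal(pr$theta[1], -0.7, tolerance = 1e-9)
  }
})

test_that("stride sampling takes every second vertex starting at the first", {
  fps <- 30; T <- 120
  sig <- cos(2 * pi * 1 * (0:(T - 1)) / fps)
  V <- 7
  vss <- structure(list(signals = matrix(rep(sig, each = V), V), fps = fps,
                        vertex_pixel_counts = rep(1L, V),
                        vertices = cbind(1:V, 1:V)),
                   class = "vertex_signals")
  pr <- vertex_phase(vss, heart_bin = 4L, stride = 2L)
  expect_equal(pr$sampled_idx, c(1L, 3L, 5L, 7L))
})

test_that("pairwise phase differences reproduce known per-vertex delays", {
  # noiseless propagation with delay an exact multiple of the frame interval
  fps <- 30; T <- 300; f_heart <- 1          # bin 10
  t <- (0:(T - 1)) / fps
  delays <- (0:4) * 2 / fps                  # 2 frames per vertex
  sig <- t(vapply(delays, function(dt) {
    pump_waveform(t - dt, period = 1, on_fraction = 1 / 3, smooth_sigma = 0.05)
  }, numeric(T)))
  vss <- structure(list(signals = sig, fps = fps,
                        vertex_pixel_counts = rep(1L, 5),
                        vertices = cbind(rep(1, 5), 1:5)),
                   class = "vertex_signals")
  pr <- vertex_phase(vss, heart_bin = 10L, stride = 1L)
  dd <- diff(pr$theta)
  expected <- -2 * pi * f_heart * 2 / fps
  expect_true(all(abs(dd - expected) < 1e-3))
})
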