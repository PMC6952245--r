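# vesselflow

Determining the direction of blood flow through a vessel is critical in
neurovascular surgery — clipping the wrong branch of an arteriovenous
malformation, for instance, can cause severe complications — yet feeders and
drainers are often visually indistinguishable. Existing intraoperative aids
(fluorescent videoangiography, Doppler ultrasound, AR overlays of
preoperative imaging) each carry workflow or safety costs. `vesselflow`
infers flow direction from nothing but a few seconds of ordinary
surgical-microscope video and a vessel segmentation drawn on one frame.

## Method

Pulsatile blood volume modulates green-channel absorption (oxyhemoglobin
absorbs most strongly in the green range), and this photoplethysmographic
modulation propagates along the vessel with the pulse wave. The pipeline:

1. **Stabilize** — register every frame to the reference frame with a
   6-parameter affine transform estimated by differential (gradient-based,
   coarse-to-fine) motion estimation.
2. **Enhance** — Eulerian colour magnification: with reference frame
   **I** (per-pixel temporal mean) and deviation δ_t = I_t − **I**
   band-passed to 0.8–3 Hz, output I′_t = I_t + α δ_t (default α = 50).
3. **Centerline** — thin the vessel labelmap to a structural skeleton,
   trace it into an ordered pixel path by a two-pass traversal, and
   downsample by a factor k (default 25) into a polyline.
4. **Signals** — each mask pixel is assigned to its nearest polyline
   vertex; per frame, each vertex receives the mean green intensity of its
   pixels. The heart rate f_heart is the highest-magnitude in-band DFT
   component of the vessel-average signal.
5. **Direction** — at every second vertex, the phase θ of the vertex
   signal's DFT coefficient at the heart-rate bin is computed
   (Z = |Z| e^{jθ}); a delay Δt shifts phase by Δθ = −2π f Δt, so θ
   decreases downstream. An adjacent-pair difference is trusted only inside
   the reliability window

   2π f_heart / f_video ≤ |Δθ| ≤ π

   (below: unresolvable at the frame rate; above: phase wrapping). Each
   accepted pair points from higher to lower θ; the overall call is the
   majority vote, and *indeterminate* is an explicit outcome.
6. **Annotate** — arrows over the accepted pairs on a representative frame,
   plus a phase colourmap of the vessel region.

A synthetic phantom generator (`generate_vessel_video()`) emulates a
pump-driven vessel phantom — a 1 s cardiac cycle, on for 1/3 s and off for
2/3 s, propagating along a straight or S-curved tube with configurable wave
speed, noise and camera jitter — and records full ground truth, so every
stage is testable without clinical data.

## Worked example

```r
library(vesselflow)

phantom <- generate_vessel_video(synth_config(fps = 60, duration = 8, seed = 7))
fit <- vesselflow(phantom$clip, phantom$mask,
                  config = flow_config(stabilize = list(enabled = FALSE)))
summary(fit)
direction_correct(fit, phantom$truth)
```

```
Blood-flow direction analysis
  heart rate: 1.000 Hz (60.0 bpm)
  vertices: 5 (polyline), 3 sampled
  pairs: 2 accepted of 2
  overall direction: backward, from (40, 12) toward (40, 108) [row, col]

Per-pair phase differences:
  pair dtheta   status direction
 v1-v3 1.9349 accepted  backward
 v3-v5 1.8008 accepted  backward

Reliability window: 0.1047 <= |dtheta| <= 3.1416 rad

correct vs ground truth: TRUE
```

The pump period is recovered exactly (1 Hz at 60 fps). Both adjacent-vertex
phase differences fall inside the reliability window `[2π·1/60, π]` =
`[0.1047, 3.1416]`, and both vote for the same physical direction: upstream
at image point (row 40, col 12) — which matches the end the simulated pulse
entered from. ("forward"/"backward" are labels relative to the traced
polyline's vertex order; the physical answer is the upstream → downstream
coordinate pair, which `direction_correct()` checks against ground truth.)

For file-based use, `run_pipeline()` (or the thin CLI at
`inst/cli/vesselflow.R`) reads a directory of numbered PNG/TIFF frames plus
a mask PNG and writes `result.json`, `annotated.png` and `phase_map.png`.

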