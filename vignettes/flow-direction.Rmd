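---
title: "Inferring blood-flow direction from pulse-wave phase in microscope video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring blood-flow direction from pulse-wave phase in microscope video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselflow)
```

## The model

Blood volume in a vessel rises and falls with each cardiac cycle, and
oxyhemoglobin absorbs green light strongly, so the green channel of a video
of an exposed vessel carries a weak periodic intensity modulation — a
photoplethysmographic signal. The pulse wave travels along the vessel at a
finite speed, so the modulation at a downstream point is a *delayed* copy of
the modulation upstream. In the Fourier domain a delay of $\Delta t$
seconds shifts the phase of the component at frequency $f$ by

$$\Delta\theta = -2\pi f \,\Delta t ,$$

so at the heart-rate frequency the phase $\theta$ of the vertex signal,
defined through $Z = |Z| e^{j\theta}$ with $\theta \in [-\pi, \pi]$,
decreases monotonically along the direction of flow. Direction inference
reduces to: estimate $f_\mathrm{heart}$, compute $\theta$ at points along
the vessel, and read the sign of adjacent differences — from higher to
lower phase.

Two error modes bound what a difference can be trusted to mean. A camera
sampling at $f_\mathrm{video}$ cannot resolve delays below one frame
interval, so differences smaller than $2\pi f_\mathrm{heart} /
f_\mathrm{video}$ are attributed to noise. And because $\theta$ is a
principal-value angle, a true decrease can appear as a jump of nearly
$2\pi$ across the $\pm\pi$ boundary (phase wrapping); differences with
magnitude above $\pi$ are therefore rejected rather than unwrapped —
unwrapping would silently convert wrapped pairs into plausible-looking
accepted ones. The acceptance window is

$$\frac{2\pi f_\mathrm{heart}}{f_\mathrm{video}} \le |\Delta\theta| \le \pi .$$

Each accepted adjacent pair votes for a direction; the overall call is the
unweighted majority, and a tie or an empty set of accepted pairs yields an
explicit *indeterminate* answer. Majority voting is the minimal aggregation
rule consistent with drawing independent per-pair arrows; pairs are formed
between consecutive *sampled* vertices (every second polyline vertex),
which matches arrows that span polyline vertices.

## Pipeline stages and their parameters

**Stabilization.** Every frame is registered to the reference frame (the
frame the segmentation was drawn on, default the first) with a 6-parameter
affine transform estimated by gradient-based Gauss–Newton iteration on a
3-level image pyramid, at most 50 iterations per level, converged when the
parameter update falls below $10^{-4}$. Warping uses bilinear interpolation
with edge replication, so no dark borders contaminate vertex means.
Estimation uses the whole frame (a region-of-interest variant would be the
natural extension for scenes with moving instruments). Two safeguards
matter in practice:

* *Sub-quarter-pixel dead zone.* On a pulsing scene, brightness change
  masquerades as tiny apparent motion in any differential estimator.
  Estimates whose largest displacement anywhere in the frame is below
  0.25 px are treated as identity — warping at that scale blurs more than
  it stabilizes. This is why disabling stabilization on a jitter-free clip
  changes the final phase differences by less than $10^{-6}$ rad.
* *Divergence fallback.* If warping a frame raises its residual (mean
  absolute difference to the reference within the dilated mask), the frame
  passes through unwarped with a warning.

A separate, deliberately simple residual-motion suppressor
(`attenuate_residual_motion()`) estimates each frame's global translation,
low-pass filters that trajectory below a cutoff (default 0.5 Hz, under the
analysis band), and cancels only the slow component. Colour content in the
0.8–3 Hz band passes through untouched. This is the package's own
lightweight design for slow drift such as breathing motion; it makes no
attempt at the deformable, phase-based motion attenuation used in more
elaborate systems.

**Enhancement.** Eulerian colour magnification with reference frame
$\mathbf{I}$ chosen as the per-pixel temporal mean — the choice that makes
the deviation $\delta_t = I_t - \mathbf{I}$ zero-mean and the band-pass
well-posed. $\delta_t$ is filtered by an ideal (brick-wall) frequency-domain
filter to 0.8–3 Hz: wide enough to catch intraoperative heart rates outside
the normal 60–100 bpm (1–1.67 Hz) range, and an orthogonal projection, so
filtering is idempotent and an in-band sinusoid is amplified exactly
$(1+\alpha)$-fold. The magnification factor defaults to $\alpha = 50$ and
is configurable; direction inference itself is insensitive to $\alpha$
because multiplying a signal by a positive constant does not change its
phase. The spatial decomposition of full Eulerian magnification is
simplified to a single Gaussian blur of $\delta$ (default $\sigma = 3$ px,
set 0 to disable): the visual pyramid matters for display, not for vertex
means. Amplified frames are clipped to $[0,1]$ for display, but the
*un-clipped* signal path ($I_t + \alpha\delta_t$) is what downstream
analysis reads, so clipping never distorts waveforms.

**Centerline.** The labelmap is thinned to a structural skeleton
(Zhang–Suen iterative thinning, followed by a sequential cleanup that
removes pixels whose 3×3 neighbourhood stays 8-connected without them —
without the cleanup, thinning leaves redundant corner pixels on diagonal
runs and simple paths would not have vertex degree ≤ 2). Short spurs
(default < 10 px), which thinning produces at boundary irregularities of
hand-drawn polygons, are pruned. The skeleton is traced by a two-pass
traversal: walk from the first foreground pixel in column-major scan order
to a free end, then restart from that end — which guarantees a complete
end-to-end traversal of a simple path regardless of where the scan started.
At junction pixels the next neighbour is chosen in fixed clockwise order
from north, for determinism. The path is downsampled by keeping every
$k$-th pixel plus the final one ($k = 25$ by default); an optional auto
mode lowers $k$ until at least 5 vertices remain. Vertex spacing is
reported in pixels — converting to physical units requires mm-per-px
metadata the video itself does not carry.

**Signals and phase.** Mask pixels (only mask pixels — background would
dilute the plethysmographic signal) are partitioned by nearest polyline
vertex, ties to the lower index, and averaged per frame on the green
channel. The heart rate is the highest-magnitude DFT bin of the
vessel-average signal within the search band, rectangular window, no
zero-padding: $f_\mathrm{heart}$ snaps to an exact bin with resolution
$f_\mathrm{video}/T$ (0.1 Hz for a 10 s clip). The DFT sign convention is
fixed — and enforced by a property test — so that delay *decreases* phase.

## The synthetic phantom

`generate_vessel_video()` emulates a pump-driven silicone vessel phantom: a
straight or S-curved tube of configurable radius whose green channel at
arclength $s$ and time $t$ is

$$g(s, t) = g_0 - A \cdot p\!\left(t - s / v\right),$$

with $p$ a 1 s-periodic rectangular drive, on for 1/3 s and off for 2/3 s
(the approximate systolic/diastolic time fractions), $v$ the wave speed in
px/s, and $A$ the pulse amplitude (default 0.05). The tube's red channel is
elevated (dyed-red water); the pulse *dips* the green channel, as rising
blood volume raises absorption — though inference is sign-agnostic since
only relative phase matters. The drive's edges are smoothed with a Gaussian
of width 0.05 s by default (closed form via the Gaussian CDF), which
concentrates energy in the fundamental; $\sigma = 0$ reproduces the hard
on/off cycle, whose fundamental still dominates the band because the 1/3
duty cycle puts $\sin(\pi n/3)/n$ weight on harmonic $n$. Defaults: 60 fps
(30 for the clinical case), 8 s duration, per-pixel Gaussian noise
$\sigma = 0.005$ against a 0.05 pulse dip, optional slow (< 0.3 Hz)
translational camera jitter, and a mandatory seed; generation is bit-for-bit
deterministic given the seed, and all ground truth (upstream end, wave
speed, arclength parameterization by cumulative chord length at 0.25 px
steps) is recorded in the output.

What the phantom does *not* emulate — and what passing tests therefore do
not establish about clinical video: specular highlights and wet-surface
glare, deformable tissue motion, instrument intrusion, compression
artefacts of clinical recorders, heart-rate variability within a clip, and
vessels that branch. The phantom's value is that ground truth is exact, so
the *signal-processing chain* can be validated to closed-form tolerances.

## Numerical choices and degenerate inputs

* Frequencies snap to DFT bins; ties in the heart-rate search go to the
  lowest bin. Clips shorter than two periods of the lower band edge are
  refused.
* Phase differences are raw differences of principal-value angles, reported
  in $(-2\pi, 2\pi)$ and never re-wrapped; the window test does the
  rejecting. Under time reversal every phase negates (up to a constant), so
  pair differences negate *modulo* $2\pi$ — which pairs straddle the
  $\pm\pi$ boundary can change, but accepted directions flip, as a test
  asserts on every sweep configuration.
* Vertex patches at the two path ends are one-sided, so an end vertex's
  *signal* genuinely carries the mean delay of a patch whose centroid sits
  a couple of pixels inboard of the vertex. Interior pairs match the
  closed form $\Delta\theta = -2\pi f_\mathrm{heart} d / f_\mathrm{video}$
  to 0.02 rad; end pairs are validated against a brute-force
  patch-averaged oracle instead.
* A mask that erodes to nothing, an empty skeleton, a constant signal, or a
  band with no DFT bin each produce a specific error; a polyline vertex
  without assigned pixels is dropped with a warning; `indeterminate` is a
  normal return value, not an error.
* The wave-speed-to-window relation for a straight vessel: adjacent sampled
  vertices are $2k$ px apart, so the per-pair difference is
  $-2\pi f_\mathrm{heart} \cdot 2k / v$. Test problem sizes (chosen to keep
  the full suite comfortably fast): 60–80 px tall, 100–120 px wide frames,
  5–10 s clips, polyline factors 10–25.

## Known limitations

Direction is inferred per vessel segment along a single non-branching
centerline; branching trees need one mask per branch. True per-pair delays
in $(\pi, 2\pi)$ alias into the window with reversed sign — no
principal-value method can distinguish them; the practical mitigations are
higher frame rates or closer vertex spacing. The affine stabilizer handles
global camera/scene motion only. Heart-rate estimation assumes cardiac
pulsation is the dominant in-band oscillation; rhythmic instrument motion
would violate that assumption.
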