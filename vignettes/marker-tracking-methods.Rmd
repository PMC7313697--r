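---
title: "Marker tracking and joint-angle estimation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker tracking and joint-angle estimation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markermotion)
```

## The problem and the model

`markermotion` estimates joint-angle time series from a single overhead
color+depth camera observing printed color markers attached to a patient's
joints during therapy. The pipeline has four stages, each with an explicit
model:

1. **Synchronization.** Color and depth sensors run on separate clocks.
   Each color timestamp is matched to the nearest unused depth timestamp
   and the pair is kept only if the skew is at most `max_delta`
   (default 6.25 ms, the smallest inter-sensor delay the recording rig
   exhibits; anything above it risks pairing a pixel with the wrong depth
   during fast motion). Matching is greedy in temporal order, uses each
   depth frame at most once, and is idempotent: re-synchronizing retained
   pairs changes nothing.

2. **Detection.** A marker is a colored geometric shape (circle, cross,
   triangle or bar in magenta, red, green, yellow, blue or cyan) with a
   white border that isolates it from clothing and skin. Candidates are
   connected components of an HSV gate (`H` in `[0,180)`, `S,V` in
   `[0,255]`; red wraps around 180), pre-filtered by a double area
   threshold relative to the registered reference area. Each candidate is
   scored by feature z-scores against the marker's own running history
   (area, convexity, center x, y), pooled as
   `d_z = 0.4 z_area + 0.3 z_convex + 0.15 z_x + 0.15 z_y`, converted to
   `sim_z = max(0, 1 − d_z/3)` — a candidate more than three pooled
   standard deviations away is presumed not to be the marker — and blended
   with a Hu-moment shape similarity `sim_s = exp(−d_s)` as
   `sim = 0.75 sim_z + 0.25 sim_s`. Candidates under `tau_sim` are
   discarded; the best survivor wins.

3. **Tracking.** Search proceeds ROI → whole frame → Kalman estimate. The
   filter is a 4-state constant-velocity model (pixels, pixels/frame) with
   position-only observations and diagonal noise; during occlusion the
   prediction is reported with status `"estimated"`, and a drift gate
   clamps it to within `tau_drift` pixels of the last confirmed detection,
   because an uncorrected constant-velocity filter otherwise drifts
   indefinitely in the direction of the last observed motion.

4. **Kinematics.** Detected centers are back-projected through the depth
   channel (3×3 zero-excluding median) and the pinhole model; the angle at
   joint *j* between its neighbors *i* and *k* is
   `θ = arccos(u·v / |u||v|)` with `u = l_j − l_i`, `v = l_j − l_k`,
   either fully in 3D (default) or after projecting out a configured body
   plane normal (`angle_sagittal()`); for an overhead camera above a lying
   patient the image-plane projection (`normal = "z"`) corresponds to the
   sagittal-plane reading. Both are exposed because either convention is
   defensible; the 3D angle is the default since it uses all measured
   information.

Assumptions worth stating: the depth stream is registered to color
resolution (an affine pixel map can be configured for unregistered input);
depth value 0 means "no reading" and is treated as missing; markers are
mounted so that the *bounding-box center* of the shape is the anatomical
joint position (the tracker reports bounding-box centers, so a mount
offset becomes a constant angle bias); the patient lies on a table so true
marker displacement between frames is bounded.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `sync$max_delta` | 6.25 | ms | smallest observed color/depth clock offset; larger skews corrupt 3D lookup |
| `weights` | 0.4/0.3/0.15/0.15 | — | area and convexity are the most stable discriminators; position enters twice |
| `combo_weights` | 0.75/0.25 | — | z-history dominates; shape supplements when history is short |
| `z_cutoff` | 3 | σ | Gaussian-plausibility bound on candidate features |
| `tau_sim` | 0.5 | — | midpoint of the similarity range; configurable per recording |
| `area_gate` | 0.5–2.0 × ref | — | double area threshold bracketing the registered area |
| `sigma_floors` | 0.10 / 0.05 / 0.5 | frac / abs / diag | see "Numerical choices" |
| `tau_drift` | 50 | px | bound on occlusion-estimate drift; of the order of one limb width |
| `roi_scale` | 3 | bbox diagonals | vicinity searched around the previous position |
| `process_noise` / `measurement_noise` | 1e-2 / 1 | px² | mild smoothing; detections are trusted near pixel level |
| `max_lost_frames` | 75 | frames | 3 s at 25 fps before a track is declared lost |

## Numerical choices

* **Sigma floors.** The z-scores divide by a *sample* standard deviation
  of the accepted history. Early in a recording — or for any feature that
  has simply been constant — that sample σ is near zero, and the first
  quantization-level change would produce an astronomical z-score, a
  rejected candidate, and (because statistics only update on acceptance) a
  permanently stuck track. The sample σ is therefore floored at the
  scale of inherent measurement noise: 10 % of the mean area (pixel
  quantization of a shape with perimeter *P* moves the rasterized area by
  roughly *P*/2, which reaches ~17 % for small crosses), 0.05 absolute for
  convexity, and half the reference bounding-box diagonal for the center
  coordinates (sub-marker-size displacements carry no outlier
  information; the ROI already constrains position at a coarser scale).
  `zscore()` itself keeps the bare contract (cap at 1e6 when σ = 0 and
  the value moved) when no floor is passed.
* **Absolute z-scores.** The z-score definition is signed, but the pooled
  quantity is a distance and the similarity conversion requires
  `d_z ≥ 0`; the absolute value is used.
* **Warm-up.** The first accepted frame seeds the statistics with `n = 1`;
  until `n ≥ 2` all z-scores are 0 and selection rests on the shape
  similarity and the area gate.
* **Hu distance.** `d_s = Σ |1/mᵢᴬ − 1/mᵢᴮ|` with
  `mᵢ = sign(hᵢ)·log₁₀|hᵢ|` over the seven invariants, skipping
  `|hᵢ| < 1e-30` (and log-moments within 1e-12 of zero, where the
  reciprocal is unstable). Moments are computed *exactly* from the closed
  contour polygon via Green's-theorem triangle decomposition, so the
  similarity-transform invariance holds to floating-point accuracy rather
  than rasterization accuracy.
* **Ties.** Equal similarities are broken by smaller displacement from the
  last known position, then by candidate index — deterministic output is
  a design requirement.
* **Drift gate: clamp, not freeze.** When the prediction exceeds
  `tau_drift` the state position is clamped onto the gate boundary along
  the prediction direction. Clamping keeps a defined, bounded position
  (freezing would ignore the motion model entirely; dropping the track
  would lose re-acquisition context).
* **Degenerate inputs.** `arccos` arguments are clamped to `[−1, 1]`;
  zero-length limb vectors raise an error naming the joint; an all-zero
  3×3 depth neighborhood yields an explicitly missing angle row, never an
  interpolated one; a lost marker keeps being searched on the whole frame
  and re-initializes the filter (zero velocity) at the first detection
  above threshold.
* **Two thresholds named τ.** The similarity threshold and the drift
  threshold are independent parameters (`tau_sim`, `tau_drift`); they
  merely share a Greek letter in common usage.
* **Per-video statistics.** Feature histories accumulate within one
  processed stream and are not carried across recordings.

## What the synthetic scenes emulate — and what they do not

The generator reproduces the recording geometry: a camera 2 m above the
table with its axis perpendicular to it, 25 fps timestamps with a
configurable depth-clock offset, a registered depth channel, and twelve
markers (each color used twice, on distant body parts, with different
shapes) on the shoulders, elbows, wrists, hips, knees and ankles of a
lying articulated figure. Joint trajectories are sinusoids through planar
forward kinematics — all markers at one height above the table, so planar
and 3D ground-truth angles coincide and segment lengths are conserved by
construction. The default study conditions are a 960×540 image with
`fx = fy = 800` px (≈2.4 mm/px at the table), 45 mm markers (≈18 px),
60–120° trajectories with a 50-frame period, stepped lighting factors
0.9/1.0/1.1 (multiplicative on RGB, which scales V and leaves hue and
saturation untouched — shadows dim markers but do not recolor them), and
additive Gaussian pixel noise σ = 2/255. The skeleton is sized like a
small pediatric patient with legs articulating outward (abducted supine
posture) so that marker paths never collide over a full motion cycle.

Not emulated: real sensor noise statistics (depth shadowing, flying
pixels, rolling shutter), motion blur, perspective foreshortening of the
marker shapes (markers are rendered face-on), cluttered backgrounds,
skin/clothing chroma near marker hues, and marker deformation on bending
joints. Passing the synthetic suites therefore demonstrates correctness
of the algorithmic chain under the stated geometry — not field accuracy
on hospital recordings, where color calibration (the HSV ranges) is the
dominant practical difficulty.

A validation preset mirrors the physical canvas experiment: three static
markers arranged to form a known angle at 1 m depth
(`canvas_scene(120)`), letting the full pipeline's angle readout be
checked against an exact reference.

## Problem sizes used in the shipped checks

The packaged validation runs use a 100-frame canvas scene at 120° and a
300-frame, 12-marker articulated sequence (3600 detection rows, 2400
angle samples) — large enough for the running statistics, occlusion
handling and error averaging to reach steady state, small enough to run
comfortably on one CPU. Unit tests use single-marker 640×480 scenes of
5–20 frames.

## Known limitations

* The z-score history model assumes roughly stationary feature
  statistics; abrupt changes in marker scale (camera moved mid-session)
  require re-registration.
* Same-color markers are disambiguated only by position history and
  shape; two identical markers crossing paths can swap tracks.
* During occlusion the reported 3D position samples the depth map at the
  estimated pixel — usually the occluder's surface — so occluded-frame
  angles should be filtered by the `status` column before clinical
  interpretation.
* The drift gate bounds, but does not eliminate, occlusion error; long
  occlusions end in a `lost` state that requires the marker to become
  visible again.
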