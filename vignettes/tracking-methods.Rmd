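---
title: "Thermal stereo tracking of nocturnal insects: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal stereo tracking of nocturnal insects: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pesttrack3d)
```

## The problem

Nocturnal insects such as geometrid moths are active only in darkness, so
RGB video — and any illumination strong enough to support it — perturbs the
very behaviour one wants to measure. A pair of parallel thermal-infrared
cameras sidesteps the light entirely: the animals appear as small warm
blobs against a heated-plate background, and their three-dimensional flight
paths can be triangulated from the two views. The price is an image with no
colour, little texture, strong motion blur at flight speed, and a handful
of nearly identical targets that cross, perch and start abruptly.

`pesttrack3d` implements the full processing chain for this setting:

1. **Motion detection** — adaptive Gaussian-mixture background modelling,
   mask clean-up, and silhouette-size filtering;
2. **Detection fusion** — rule-based merging of appearance-detector boxes
   (e.g. from a trained CNN, supplied through a detection-file interface)
   with the motion detections;
3. **Tracking** — a population-aware tracking-by-detection algorithm with a
   velocity-adaptive IOU gate and a Kalman constant-velocity motion model;
4. **Stereo reconstruction** — pairing the two cameras' 2D tracks and
   triangulating per-frame 3D positions from the centroid disparity;
5. **Evaluation** — detection metrics (P, R, F1, AP) and CLEAR-MOT tracking
   metrics (MOTA, MOTP, identity switches) against MOT16-format ground
   truth;
6. **Synthetic scenes** — a ground-truthed stereo scene generator so every
   stage is testable end to end without camera hardware.

## Motion detection

Each pixel carries a mixture of `gmm_components = 5` Gaussians over
intensity (Stauffer–Grimson formulation). A pixel is foreground when no
reliable component — the leading components holding 90% of the weight —
explains it within `gmm_var_threshold = 16` squared-Mahalanobis units
(a 4-sigma gate). The learning rate is `1/min(t, gmm_history)` with
`gmm_history = 120` frames (4 s at 30 fps): fast enough to absorb slow
illumination drift, slow enough that a moth perched for a second or two is
still seen. These hyper-parameters are conventional background-subtraction
defaults; all are exposed in `motion_seg_config()`.

Masks are cleaned by a 3×3 median (majority) filter followed by a
morphological opening with a 3×3 square structuring element — the smallest
kernels that remove sensor speckle without eroding a 150 px² silhouette.
Both are binary-mask specialisations implemented in compiled code
(separable box counts), since general-purpose image-processing median
filters operate at full bit depth and are orders of magnitude slower on a
per-frame video loop.

Connected components (8-connectivity, so diagonally-thin silhouettes stay
whole) are kept when their pixel count lies in the inclusive band
`[area_min, area_max] = [150, 550]` px², the empirical silhouette-size
range of the target animals at the working distances; everything smaller
is clutter, everything larger is background structure or a multi-animal
merge. Kept components become motion boxes with confidence 1. The
`enhance_frame()` overlay (saturating the red channel inside motion boxes)
reproduces the contrast-enhancement step used when preparing training
images for an appearance detector.

## Detection fusion

Appearance detections below a 0.3 confidence floor are discarded as
detector noise. The remaining boxes are paired with motion candidates by
greedy nearest-centre pairing within 20 px, and three rules decide what is
a real target (all comparisons strict, as the thresholds are stated):

* **Appearance-only** boxes survive if confidence > 0.7;
* **Motion-only** candidates survive if they have persisted for more than
  30 consecutive frames (centre-linked within 20 px frame to frame);
* **Paired** boxes survive if their IOU exceeds 0.5; the output keeps the
  appearance geometry (the tighter fit) with the pair's maximum
  confidence. A pair that fails the IOU check falls back to the two solo
  rules individually.

A motion candidate confirmed by pairing keeps its persistence counter —
confirmation is not a reset. Rule 2 confirms from the crossing frame
onward only; frames accumulated before confirmation are not emitted
retroactively, since a live pipeline cannot rewrite its past output.

## Tracking

The tracker is a tracking-by-detection loop: per-track Kalman filters in
the standard 7-state box parameterisation (centre, area, aspect ratio and
rates of the first three), optimal assignment between predicted and
detected boxes on cost 1 − IOU, and two modifications for a fixed, known
population in an enclosure.

**Velocity-adaptive gate.** A match is accepted only if its IOU exceeds
`−0.025 v + 0.3`, where `v` is the Euclidean norm of the track's Kalman
centre-velocity estimate in px/frame. Slow targets must overlap well;
fast targets — whose boxes legitimately displace and deform — are matched
under a looser gate. The linear form goes non-positive at `v ≥ 12`, and a
non-positive gate would accept arbitrary non-overlap, so the gate is
clamped to `[0.05, 0.3]`; both bounds are configuration.

**Population-aware cascade.** The number of animals `n_expected` is known.
After the IOU assignment:

* more detections than animals ⇒ the surplus is false alarms; no new
  trackers are created;
* at or below the expected count, leftover detections and trackers go
  through a second optimal matching on centre Euclidean distance,
  accepting pairs within `second_match_dist = 20` px (the animals' typical
  per-frame displacement). The obvious case is an exact count with one
  leftover pair; we also run the pass in the shortfall case, because two
  simultaneous blob merges otherwise leave a tracker coasting forever next
  to its own detection, which it lost only because a speed jump broke the
  overlap gate;
* unmatched trackers coast on their constant-velocity prediction for up to
  `max_age = 20` frames before deletion, and emit no boxes while coasting
  (a gap in the exported trajectory is honest; an extrapolated box is
  not);
* new identities are seeded only while the live population is below
  `n_expected`.

Tracks are confirmed immediately (`min_hits = 1`): with a capped, seeded
population a probationary period would only delay the inevitable. With the
cascade disabled the tracker reduces to the stock algorithm — fixed 0.3
gate, unlimited seeding, deletion after `max_age_plain = 1` unmatched
frame — which is the baseline the ablation harness
(`compare_tracker_variants()`) compares against.

The assignment itself is solved exactly by dynamic programming over column
subsets (`solve_assignment()`). For the ≤ 10-row matrices that occur with a
handful of animals this is instantaneous, provably optimal, and easy to
verify against brute-force permutation enumeration (the test suite does).

## Stereo reconstruction

The rig is rectified and parallel: same intrinsics `K`, focal length `f`
(px), baseline `B` (m). Depth follows from the horizontal disparity `d`
(px) of corresponding points, `Zc = f B / d`, and the full camera-frame
position from `Pc = K⁻¹ [u, v, 1]ᵀ Zc`. Coordinates are meters in the
left-camera frame.

Tracks are paired across cameras by optimal assignment on a cost combining
the median absolute row difference over common frames (corresponding points
share a row on a rectified rig) with the temporal-overlap deficit; pairs
with median row difference above `row_epsilon = 10` px are rejected. The
per-track disparity is the difference of box-centre columns. Dense
block-matching disparity was considered and rejected: for isolated warm
blobs the centroid difference is deterministic, sub-pixel accurate, and
testable against the closed-form forward model, whereas dense matching adds
parameters without adding information where the image is featureless.

Within a paired track, frames are dropped when the disparity is
non-positive (geometrically impossible) or when the two centres violate the
epipolar row constraint by more than `row_epsilon` — the signature of one
camera seeing two animals as a single merged blob. Both drops are logged.

`trajectory_error()` summarises point-wise Euclidean distances with min,
max, mean and the sample (n − 1) standard deviation. The bundled
`led_validation_points()` data set — ten LED markers of insect-like size
hung at measured positions and located by the binocular pipeline, both in
the camera-centred frame in cm — exercises this summary: errors of
0.78–1.90 cm, mean 15 mm, SD 3.8 mm.

## Evaluation

Detection: `precision_recall_f1()` and `average_precision()` (PASCAL-style
all-point interpolation; greedy matching by descending confidence at
IOU ≥ 0.5, one match per truth box). Tracking: `clear_mot()` follows the
CLEAR protocol — correspondences persist from frame to frame while both
boxes remain within the gate, the remainder are matched by optimal
assignment, and an identity switch is counted whenever a truth target's
matched hypothesis id differs from its last one. `MOTA = 1 − (FN + FP +
IDS)/GT` may be negative; MOTP is reported both as the raw mean centre
distance of matched pairs in pixels and normalised by the matching gate,
because the raw-pixel and normalised conventions are both in circulation
and they differ by two orders of magnitude. The default gate is 50 px
centre distance; IOU-gated matching is available.

## The synthetic scene generator

The generator emulates the observation conditions the pipeline targets: a
0.30 m cubic enclosure holding 5 animals, filmed at 30 fps and 640×480 for
10 s. Flight is piecewise constant-velocity with Poisson-timed abrupt
speed/direction changes (`turn_hazard = 0.5`/s), Poisson-timed perch
intervals (`perch_hazard = 0.1`/s, 1–3 s long), speeds of 0.05–0.2 m/s
(per-frame image displacements up to ~15 px, the regime the 20 px
second-match distance is built for), and reflection at the walls.

The rig geometry is derived, not tuned: with the cube's centre 0.50 m from
the left camera, a focal length of 550 px and baseline 0.08 m are close to
the largest values for which the entire cube stays inside both camera
frusta (vertical coverage at the near face, `2 · 0.35 · 240/f ≥ 0.30`,
gives `f ≤ 560`). The blob scale of 7 mm then makes the above-half-maximum
silhouette area span almost exactly the 150–550 px² operating band across
the cube's 0.35–0.65 m depth range — the depth ratio fixes the area ratio
at 3.4, just inside the band's 3.67, so no slack exists: the silhouette
band, enclosure size and working distance jointly determine the geometry.

Targets render as anisotropic Gaussian blobs elongated along their image
velocity (`σ_along = σ + 0.5 · speed_px`, emulating exposure-time motion
blur), over a warm-plate vertical gradient with a frozen spatial texture
and per-frame Gaussian sensor noise (`noise_sd = 3` intensity levels).
Thermal imaging is modelled as intensity contrast only — the pipeline
consumes intensities, not temperatures. Perched targets remain rendered
(still warm) but are progressively absorbed by the background model, which
is exactly the situation the fusion rules arbitrate: the appearance
detector holds perched targets while the motion chain holds flying ones.

Exported 2D ground truth is the exact pinhole projection of the 3D paths;
rendered-blob ground truth boxes are the above-half-maximum extents centred
on those projections.

**What the generator does not emulate:** wing articulation and
pose-dependent silhouette shape, radiometric temperature structure,
occlusion beyond additive blob overlap, heating-plate inhomogeneity, and
camera synchronisation error. Passing end-to-end tests on these scenes
therefore demonstrates the pipeline's geometric and data-association
correctness, not detector robustness on real thermal imagery.

## Numerical and degenerate-input choices

* Pixel coordinates are 0-based, origin top-left, x rightward, y downward;
  boxes are `(x, y, w, h)` with sub-pixel values allowed in memory and
  fixed-precision decimals in files. Frames are 1-based in MOT16 files,
  0-based in memory; conversion happens at the I/O boundary only.
* Size-band bounds are inclusive on both ends.
* Assignment ties break toward the earlier row/column; greedy pairing ties
  break toward the lower box index.
* The Kalman area state is floored at a small positive value and its rate
  zeroed when a prediction would drive the area non-positive.
* Degenerate metric denominators (no detections, no truth) yield 0 with a
  warning rather than NaN; empty files read as empty record sets; a
  single-frame sequence yields a defined (all-background) mask.
* `solve_assignment()` treats non-finite costs as forbidden pairs and
  falls back to the largest feasible matching cardinality.

## Problem sizes used in the shipped tests

The test suite and the acceptance script regenerate everything they
measure: a 10 s, 5-target default scene for the end-to-end run; twenty
6 s stressed detection streams (10% dropout, 1 px jitter, 0.5
spurious boxes/frame on average) for the tracker ablation; 1000-point
Monte-Carlo draws for stereo error propagation; and exhaustive
enumeration oracles on scenes of up to 3 targets × 4 frames for the
CLEAR-MOT implementation. These sizes give stable statistics while keeping
a full run in the low minutes on one core.

## Known limitations

* When two animals' blobs merge in one camera for longer than the
  20-frame retention window, the specified tracker cannot preserve both
  identities — the detector sees one box, the coasting tracker dies, and
  the reappearing animal is necessarily re-seeded. Crowded default scenes
  therefore show a handful of identity switches even at low noise; the
  per-frame epipolar gate keeps the resulting 3D error small, but identity
  continuity through long merges would require an appearance model, which
  is deliberately out of scope for shape-changing thermal blobs.
* MOTP's published scale convention is ambiguous; both conventions are
  reported and the raw-pixel form is the default.
* The stereo path assumes an upstream-rectified rig; lens distortion and
  rectification residuals are not modelled.
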