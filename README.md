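# pesttrack3d

Multi-target 3D trajectory tracking of nocturnal insects in stereo
thermal-infrared video.

Nocturnal pests (geometrid moths and their kin) are active only in
darkness, where RGB cameras either fail or perturb the behaviour being
studied. Filmed instead by two parallel thermal-infrared cameras over a
warm plate, the animals appear as small, blurred, texture-free warm blobs —
and their three-dimensional flight paths can be recovered by detection,
tracking and stereo triangulation. `pesttrack3d` implements that pipeline
for behavioural researchers and plant-protection labs:

* **Motion detection** — per-pixel Gaussian-mixture background modelling,
  median + opening mask clean-up, and silhouette-size filtering to the
  150–550 px² operating band, plus red-channel contrast enhancement of
  moving targets.
* **Detection fusion** — appearance-detector boxes (from any trained
  detector, via MOTChallenge-style CSV) are merged with motion detections
  by three confirmation rules: solo appearance confidence > 0.7, motion
  persistence > 30 frames, or a centre-gated (20 px) pair with
  IOU > 0.5.
* **Tracking** — Kalman constant-velocity motion models and optimal
  (Hungarian-equivalent) IOU association, extended with a
  velocity-adaptive acceptance gate, `IOU_min = clamp(−0.025 v + 0.3)`,
  and a population-aware cascade for a known number of animals: surplus
  detections are discarded, leftovers are re-matched by Euclidean distance
  (≤ 20 px), and unmatched trackers coast for up to 20 frames.
* **Stereo reconstruction** — track pairing across the rectified rig by
  the shared-row constraint, then per-frame depth `Zc = f·B/d` from the
  centroid disparity and back-projection `Pc = K⁻¹[u, v, 1]ᵀ Zc`.
* **Evaluation** — P/R/F1/AP detection metrics and CLEAR-MOT tracking
  metrics (`MOTA = 1 − (FN+FP+IDS)/GT`, MOTP in raw-pixel and normalised
  conventions) against MOT16-format ground truth, with an ablation harness
  over the tracker variants.
* **Synthetic scenes** — a seeded generator of ground-truthed stereo
  thermal scenes (warm blobs with motion blur and sensor noise in a
  0.30 m cube) so the entire pipeline is testable without hardware.

See `vignettes/tracking-methods.Rmd` for the models, parameter meanings and
design rationale.

## Worked example

Simulate a short stereo scene, run the full pipeline, and score it against
the generator's ground truth:

```r
library(pesttrack3d)

sc    <- scene_config(duration_s = 3, n_targets = 4, rng_seed = 2)
rig   <- default_rig(sc)
scene <- render_stereo(simulate_paths(sc, rig), rig, sc)

res <- run_pipeline(scene, rig, sc)     # detect -> fuse -> track -> triangulate
s   <- score_trajectories(res$trajectories, scene$gt3d)
m   <- clear_mot(scene$gt2d$left, res$left$records, gate = 50)

cat(sprintf("tracks: %d   mean 3D error: %.2f mm   MOTA: %.2f   IDS: %d\n",
    length(unique(res$trajectories$track_id)), 1000 * s$mean, m$mota, m$ids))
#> tracks: 4   mean 3D error: 1.95 mm   MOTA: 1.00   IDS: 0

head(res$trajectories, 3)
#>   track_id frame          Xc         Yc        Zc
#> 1        1     0 -0.03976331 0.05207101 0.5207101
#> 2        1     1 -0.03717673 0.04988257 0.5176474
#> 3        1     2 -0.03525442 0.04798356 0.5174682
```

All four animals are recovered as single identities; the mean 3D error of
about 2 mm reflects sub-pixel centroid noise propagated through the
`Zc = f·B/d` triangulation at ~0.5 m range.

The bundled LED validation set (ten insect-sized markers at tape-measured
positions, located independently by the binocular pipeline) checks the 3D
error summary:

```r
led <- led_validation_points()
err <- trajectory_error(led[, c("tx","ty","tz")], led[, c("ax","ay","az")])
round(err$distances, 2)   # cm
#>  [1] 1.90 1.46 1.36 0.78 1.82 1.85 1.60 1.72 1.27 0.97
cat(sprintf("min %.0f mm  max %.0f mm  mean %.0f mm  sd %.1f mm\n",
    10*err$min, 10*err$max, 10*err$mean, 10*err$sd))
#> min 8 mm  max 19 mm  mean 15 mm  sd 3.8 mm
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/pesttrack` (subcommands `simulate`, `detect-motion`, `fuse`,
`track`, `reconstruct`, `evaluate`, `pipeline`; see
`pt_cli("--help")`).

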