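test_that("path simulation is deterministic and respects degenerate kinematics", {
  sc <- scene_config(duration_s = 2, rng_seed = 42)
  rig <- default_rig(sc)
  p1 <- simulate_paths(sc, rig)
  p2 <- simulate_paths(sc, rig)
  expect_identical(p1, p2)
  expect_equal(p1$n_frames, 60)

  # zero speed range: constant paths
  sc0 <- scene_config(duration_s = 1, speed_range = c(0, 0), rng_seed = 3)
  p0 <- simulate_paths(sc0, default_rig(sc0))
  for (k in seq_len(sc0$n_targets))
    expect_equal(apply(p0$positions[, k, ], 2, stats::var), rep(0, 3),
                 tolerance = 1e-20)
})

test_that("paths stay inside the box volume", {
  sc <- scene_config(duration_s = 5, rng_seed = 9)
  rig <- default_rig(sc)
  p <- simulate_paths(sc, rig)
  half <- sc$box_side / 2
  ctr <- c(rig$B / 2, 0, sc$box_center_z)
  for (ax in 1:3) {
    expect_true(all(abs(p$positions[, , ax] - ctr[ax]) <= half + 1e-9))
  }
})

test_that("direction-change counts follow the configured hazard", {
  # with hazard h per second over T seconds, jump count is ~Poisson(h T);
  # averaged over seeds the observed mean must sit within 3 SD
  h <- 0.5; T <- 30
  n_seeds <- 40
  counts <- vapply(seq_len(n_seeds), function(s) {
    # huge box so no wall reflections contaminate the jump count
    sc <- scene_config(duration_s = T, n_targets = 1, turn_hazard = h,
                       perch_hazard = 0, box_side = 50, box_center_z = 30,
                       rng_seed = 1000 + s)
    p <- simulate_paths(sc, default_rig(sc))
    v <- diff(p$positions[, 1, ])
    # velocity changes (beyond reflection) mark jumps; count distinct speed
    # magnitudes changes
    sp <- sqrt(rowSums(v^2))
    sum(abs(diff(sp)) > 1e-9)
  }, numeric(1))
  lambda <- h * T
  se <- sqrt(lambda / n_seeds)
  expect_lt(abs(mean(counts) - lambda), 3.5 * se + 3)
})

test_that("exported 2D ground truth is the exact pinhole projection of 3D", {
  sc <- scene_config(duration_s = 1, rng_seed = 6)
  rig <- default_rig(sc)
  p <- simulate_paths(sc, rig)
  scene <- render_stereo(p, rig, sc)
  for (cam in c("left", "right")) {
    g <- scene$gt2d[[cam]]
    for (k in seq_len(sc$n_targets)) {
      gk <- g[g$id == k, ]
      uv <- project_points(p$positions[, k, ], rig, cam)
      expect_equal(gk$x + gk$w / 2, uv[, 1], tolerance = 1e-9)
      expect_equal(gk$y + gk$h / 2, uv[, 2], tolerance = 1e-9)
    }
  }
})

test_that("a static centered target renders at the stereo-consistent columns", {
  sc <- scene_config(duration_s = 0.2, n_targets = 1, speed_range = c(0, 0),
                     noise_sd = 0, blur_gain = 0, rng_seed = 5)
  rig <- default_rig(sc)
  p <- simulate_paths(sc, rig)
  scene <- render_stereo(p, rig, sc)
  Z <- p$positions[1, 1, 3]
  find_peak <- function(img) {
    i <- which(img == max(img), arr.ind = TRUE)[1, ]
    c(u = i[["col"]] - 1, v = i[["row"]] - 1)
  }
  pl <- find_peak(scene$left[[3]])
  pr <- find_peak(scene$right[[3]])
  expect_equal(pl[["v"]], pr[["v"]], tolerance = 1)
  expect_equal(pl[["u"]] - pr[["u"]], rig$f * rig$B / Z, tolerance = 1)
  # noise- and blur-free blob peak sits at the projected center (sub-pixel
  # via intensity-weighted centroid around the peak)
  uv <- project_points(matrix(p$positions[1, 1, ], 1), rig, "left")
  img <- scene$left[[3]]
  win <- img[(pl[["v"]] - 3):(pl[["v"]] + 5), (pl[["u"]] - 3):(pl[["u"]] + 5)]
  win <- win - min(win)
  cu <- sum(col(win) * win) / sum(win) + pl[["u"]] - 4
  cv <- sum(row(win) * win) / sum(win) + pl[["v"]] - 4
  expect_equal(cu, uv[1], tolerance = 0.5)
  expect_equal(cv, uv[2], tolerance = 0.5)
})

test_that("unblurred silhouette areas span the configured size band", {
  sc <- scene_config(rng_seed = 14)
  rig <- default_rig(sc)
  # above-half-maximum pixel area of an isotropic Gaussian blob of scale
  # sigma_px is pi (1.1774 sigma)^2; across the admissible depth range it
  # must stay inside [150, 550]
  Z <- seq(sc$box_center_z - sc$box_side / 2, sc$box_center_z + sc$box_side / 2,
           length.out = 50)
  s_px <- rig$f * sc$blob_sigma_m / Z
  area <- pi * (1.1774 * s_px)^2
  expect_true(all(area >= 150 & area <= 550))
})

test_that("ground-truth exports round-trip through the readers", {
  sc <- scene_config(duration_s = 1, rng_seed = 21)
  rig <- default_rig(sc)
  p <- simulate_paths(sc, rig)
  scene <- render_stereo(p, rig, sc)
  dir <- withr::local_tempdir()
  paths <- export_ground_truth(scene, dir)
  gl <- read_mot16(paths["gt_left"])
  expect_equal(nrow(gl), nrow(scene$gt2d$left))
  expect_equal(sort(unique(gl$frame)), 0:(p$n_frames - 1))
  expect_equal(gl$x, scene$gt2d$left$x[order(scene$gt2d$left$frame,
                                             scene$gt2d$left$id)],
               tolerance = 1e-4)
  g3 <- read_trajectory3d(paths["gt3d"])
  expect_equal(nrow(g3), p$n_frames * sc$n_targets)
})

test_that("the stand-in detector finds rendered targets with high confidence", {
  sc <- scene_config(duration_s = 1, rng_seed = 30)
  rig <- default_rig(sc)
  p <- simulate_paths(sc, rig)
  scene <- render_stereo(p, rig, sc)
  det <- standin_detector(scene$left, sc, scene$background)
  per_frame <- tabulate(det$frame + 1, p$n_frames)
  expect_gte(stats::median(per_frame), sc$n_targets - 1)
  expect_true(all(det$conf > 0.7))
  # detected centers sit near ground-truth centers
  g0 <- scene$gt2d$left[scene$gt2d$left$frame == 5, ]
  d0 <- det[det$frame == 5, ]
  D <- sqrt(outer(d0$x + d0$w / 2, g0$x + g0$w / 2, "-")^2 +
              outer(d0$y + d0$h / 2, g0$y + g0$h / 2, "-")^2)
  expect_lt(max(apply(D, 1, min)), 5)
})

test_that("corrupt_detections applies dropout and spurious boxes as configured", {
  gt <- linear_stream(n_targets = 4, n_frames = 100)
  det <- corrupt_detections(gt, 100, dropout = 0.3, spurious_rate = 1,
                            seed = 2)
  expect_lt(nrow(det[det$conf == 0.9 & det$w > 15, ]), nrow(gt) + 150)
  expect_true(all(det$id == -1L))
  # determinism
  expect_identical(det, corrupt_detections(gt, 100, dropout = 0.3,
                                           spurious_rate = 1, seed = 2))
})
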