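test_that("the speed-dependent IOU gate is linear, clamped and monotone", {
  cfg <- tracker_config()
  expect_equal(dynamic_iou_threshold(0, cfg), 0.3)
  expect_equal(dynamic_iou_threshold(4, cfg), 0.2)
  expect_equal(dynamic_iou_threshold(20, cfg), cfg$iou_floor)
  v <- seq(0, 40, by = 0.25)
  thr <- dynamic_iou_threshold(v, cfg)
  expect_true(all(diff(thr) <= 0))
  expect_true(all(thr >= cfg$iou_floor & thr <= cfg$iou_ceiling))
  # unclamped segment decreases by exactly 0.025 per px/frame
  lin <- v <= (cfg$iou_intercept - cfg$iou_floor) / -cfg$iou_slope
  expect_equal(diff(thr[lin]) / 0.25, rep(-0.025, sum(lin) - 1))
  expect_error(dynamic_iou_threshold(-1, cfg), "non-negative")
})

test_that("Kalman prediction is constant-velocity in center and area", {
  b <- bounding_boxes(0, 100, 50, 20, 10)
  tr <- pesttrack3d:::new_track(1L, b)
  # freshly initialised: prediction equals the initialising detection
  p <- predict_track(tr)
  expect_equal(c(p$box$x, p$box$y, p$box$w, p$box$h),
               c(100, 50, 20, 10), tolerance = 1e-8)
  # zero velocity: repeated prediction stays put
  p2 <- predict_track(p$track)
  expect_equal(p2$box$x, 100, tolerance = 1e-8)

  # after updates implying center velocity (3, 4), prediction shifts
  tr <- pesttrack3d:::new_track(1L, b)
  for (i in 1:25) {
    tr <- predict_track(tr)$track
    det <- bounding_boxes(i, 100 + 3 * i, 50 + 4 * i, 20, 10)
    tr$kf <- pesttrack3d:::kf_update(tr$kf, det)
  }
  v <- pesttrack3d:::kf_speed(tr$kf)
  expect_equal(v, 5, tolerance = 0.05)
  p <- predict_track(tr)
  expect_equal(p$box$x + p$box$w / 2, 100 + 3 * 26 + 10, tolerance = 0.5)
  expect_equal(p$box$y + p$box$h / 2, 50 + 4 * 26 + 5, tolerance = 0.5)
})

test_that("association applies the velocity-dependent gate", {
  cfg <- tracker_config()
  mk_track <- function(v = 0) {
    tr <- pesttrack3d:::new_track(1L, bounding_boxes(0, 100, 100, 20, 20))
    tr$kf$x[5] <- v      # center-velocity x component, px/frame
    tr$predicted <- pesttrack3d:::z_to_box(tr$kf$x[1:4])
    tr
  }
  det_iou <- function(target_iou) {
    # shift a 20x20 box right by dx so IOU = (20-dx)/(20+dx)
    dx <- 20 * (1 - target_iou) / (1 + target_iou)
    bounding_boxes(1, 90 + dx, 90, 20, 20)
  }
  a <- associate(list(mk_track(0)), det_iou(0.4), cfg)
  expect_equal(nrow(a$matches), 1)
  a <- associate(list(mk_track(0)), det_iou(0.25), cfg)
  expect_equal(nrow(a$matches), 0)
  expect_equal(a$unmatched_tracks, 1)
  expect_equal(a$unmatched_detections, 1)
  a <- associate(list(mk_track(4)), det_iou(0.25), cfg)  # gate drops to 0.2
  expect_equal(nrow(a$matches), 1)
})

test_that("assignment is globally optimal (vs brute force) on small matrices", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(1:5, 1); m <- sample(1:5, 1)
    cost <- matrix(runif(n * m), n, m)
    a <- solve_assignment(cost)
    bf <- assignment_bruteforce(cost)
    tot <- sum(cost[cbind(which(!is.na(a)), a[!is.na(a)])])
    expect_equal(tot, bf$cost, tolerance = 1e-12)
  }
  # forbidden pairs
  cost <- matrix(c(Inf, 1, 1, Inf), 2, 2)
  expect_equal(solve_assignment(cost), c(2L, 1L))
})

test_that("the cascade discards surplus detections and caps the population", {
  cfg <- tracker_config(n_expected = 5)
  det0 <- bounding_boxes(rep(0, 5), x = seq(0, 400, 100), y = 100, w = 20, h = 20)
  tracks <- track_sequence(det0, 1, cfg)
  expect_length(tracks, 5)
  # 6 detections at the next frame: surplus discarded, still 5 tracks
  det1 <- bounding_boxes(rep(1, 6), x = c(seq(0, 400, 100), 550), y = 100,
                         w = 20, h = 20)
  tracks <- track_sequence(rbind(det0, det1), 2, cfg)
  expect_length(tracks, 5)
})

test_that("the second matching pairs leftovers within 20 px and not beyond", {
  cfg <- tracker_config(n_expected = 2)
  # frame 0: two targets; frame 1: one jumps 15 px (IOU with 10x10 box =
  # 0; second match must catch it), the other stays
  d0 <- bounding_boxes(rep(0, 2), x = c(100, 300), y = 100, w = 10, h = 10)
  d1 <- bounding_boxes(rep(1, 2), x = c(115, 300), y = 100, w = 10, h = 10)
  tracks <- track_sequence(rbind(d0, d1), 2, cfg)
  rec <- tracks_to_records(tracks)
  expect_length(unique(rec$id), 2)
  expect_equal(sum(rec$frame == 1), 2)   # both tracks updated at frame 1

  # a 25 px jump exceeds the threshold: the track coasts instead
  d1b <- bounding_boxes(rep(1, 2), x = c(125, 300), y = 100, w = 10, h = 10)
  tracks <- track_sequence(rbind(d0, d1b), 2, cfg)
  rec <- tracks_to_records(tracks)
  expect_equal(sum(rec$frame == 1), 1)
})

test_that("coasting trackers survive gaps up to 20 frames and resume their ID", {
  cfg <- tracker_config(n_expected = 2)
  mk <- function(frames, x0, step, y) {
    bounding_boxes(frame = frames, x = x0 + step * frames, y = y,
                   w = 20, h = 20)
  }
  full <- 0:59
  gap <- setdiff(full, 20:29)  # target 2 missing for 10 frames
  det <- rbind(mk(full, 10, 2, 50), mk(gap, 10, 2, 300))
  det <- det[order(det$frame), ]
  tracks <- track_sequence(det, 60, cfg)
  rec <- tracks_to_records(tracks)
  expect_length(unique(rec$id), 2)
  id2 <- unique(rec$id[rec$y > 200])
  expect_length(id2, 1)  # same ID before and after the gap
  # no boxes emitted during the coast
  expect_equal(sort(unique(rec$frame[rec$id == id2])), gap)

  # absence beyond max_age deletes the track; a fresh ID appears after
  gap2 <- setdiff(full, 20:45)  # 26-frame absence > 20
  det2 <- rbind(mk(full, 10, 2, 50), mk(gap2, 10, 2, 300))
  det2 <- det2[order(det2$frame), ]
  tracks2 <- track_sequence(det2, 60, cfg)
  rec2 <- tracks_to_records(tracks2)
  ids_far <- unique(rec2$id[rec2$y > 200])
  expect_length(ids_far, 2)
})

test_that("unambiguous linear streams track perfectly and deterministically", {
  det <- linear_stream(n_targets = 5, n_frames = 100)
  det$id <- -1L
  cfg <- tracker_config(n_expected = 5)
  rec1 <- tracks_to_records(track_sequence(det, 100, cfg))
  rec2 <- tracks_to_records(track_sequence(det, 100, cfg))
  expect_identical(rec1, rec2)
  expect_length(unique(rec1$id), 5)
  gt <- linear_stream(n_targets = 5, n_frames = 100)
  m <- clear_mot(gt, rec1, gate = 50)
  expect_equal(m$mota, 1)
  expect_equal(m$ids, 0)
})

test_that("the dynamic gate survives an abrupt speed jump that a fixed gate fragments", {
  # one target accelerating 3x mid-sequence; boxes small so overlap drops
  n <- 60
  xs <- cumsum(c(0, ifelse(seq_len(n - 1) < 30, 4, 12)))
  det <- bounding_boxes(frame = 0:(n - 1), x = 10 + xs, y = 100, w = 16,
                        h = 16)
  gt <- det; gt$id <- 1L
  cfg <- tracker_config(n_expected = 1)
  rec_dyn <- tracks_to_records(track_sequence(det, n, cfg, dynamic_iou = TRUE,
                                              cascade = TRUE))
  rec_fix <- tracks_to_records(track_sequence(det, n, cfg, dynamic_iou = FALSE,
                                              cascade = FALSE))
  m_dyn <- clear_mot(gt, rec_dyn, gate = 30)
  m_fix <- clear_mot(gt, rec_fix, gate = 30)
  # dynamic gating keeps one identity; the fixed gate misses matches or
  # fragments the track
  expect_length(unique(rec_dyn$id), 1)
  expect_gt(m_dyn$mota, m_fix$mota)
})

test_that("tracker count never exceeds the expected population", {
  set.seed(41)
  gt <- linear_stream(n_targets = 5, n_frames = 80)
  det <- corrupt_detections(gt, 80, dropout = 0.2, jitter_px = 2,
                            spurious_rate = 1, seed = 5)
  cfg <- tracker_config(n_expected = 5)
  tracks <- track_sequence(det, 80, cfg)
  rec <- tracks_to_records(tracks)
  per_frame <- table(rec$frame)
  expect_true(all(per_frame <= 5))
  # the returned set may include replaced (dead) identities, but no more
  # than n_expected can ever be live at once
  for (f in c(20, 50, 79))
    expect_lte(length(unique(rec$id[rec$frame == f])), 5)
})
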