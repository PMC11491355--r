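test_that("iou matches hand and brute-force values", {
  a <- bounding_boxes(0, 0, 0, 10, 10)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, bounding_boxes(0, 20, 20, 5, 5)), 0)
  expect_equal(iou(a, bounding_boxes(0, 5, 0, 10, 10)), 50 / 150)

  set.seed(7)
  for (i in 1:25) {
    b1 <- bounding_boxes(0, sample(0:20, 1), sample(0:20, 1),
                         sample(1:15, 1), sample(1:15, 1))
    b2 <- bounding_boxes(0, sample(0:20, 1), sample(0:20, 1),
                         sample(1:15, 1), sample(1:15, 1))
    expect_equal(iou(b1, b2), iou_bruteforce(b1, b2), tolerance = 1e-12)
    expect_equal(iou(b1, b2), iou(b2, b1))
  }
})

test_that("motion candidates accumulate, reset and resolve contention", {
  cfg <- fusion_config()
  b <- function(x) bounding_boxes(0, x, 50, 10, 10, conf = 1, source = "motion")
  cand <- update_motion_candidates(NULL, b(100), cfg)
  cand <- update_motion_candidates(cand, b(101), cfg)
  cand <- update_motion_candidates(cand, b(102), cfg)
  expect_equal(cand$consecutive_frames, 3L)

  cand <- update_motion_candidates(cand, b(300), cfg)  # 200 px jump
  expect_equal(cand$consecutive_frames, 1L)

  # two new boxes near one old candidate: nearest wins, other starts fresh
  cand <- update_motion_candidates(NULL, b(100), cfg)
  cand <- update_motion_candidates(cand, rbind(b(103), b(98)), cfg)
  expect_equal(cand$consecutive_frames[order(cand$x)], c(2L, 1L))

  # no boxes: all candidates dropped
  cand <- update_motion_candidates(cand, empty_boxes(), cfg)
  expect_equal(nrow(cand), 0L)
})

test_that("the three confirmation rules behave as specified", {
  cfg <- fusion_config()
  app <- function(conf, x = 100) bounding_boxes(0, x, 100, 20, 20, conf = conf)
  mot <- function(count, x = 100) {
    m <- bounding_boxes(0, x, 100, 20, 20, conf = 1, source = "motion")
    m$consecutive_frames <- count
    m
  }
  # rule 1: solo appearance needs conf > 0.7
  expect_equal(nrow(fuse(app(0.8), NULL, cfg)), 1)
  expect_equal(nrow(fuse(app(0.5), NULL, cfg)), 0)
  expect_equal(nrow(fuse(app(0.7), NULL, cfg)), 0)   # strict
  # rule 2: solo motion needs count > 30
  expect_equal(nrow(fuse(empty_boxes(), mot(35), cfg)), 1)
  expect_equal(nrow(fuse(empty_boxes(), mot(10), cfg)), 0)
  expect_equal(nrow(fuse(empty_boxes(), mot(30), cfg)), 0) # strict
  # rule 3: gated pair with IOU > 0.5 confirms, takes appearance geometry
  # and max confidence
  out <- fuse(app(0.4, x = 100), mot(5, x = 105), cfg)  # centers 5 px, IOU 0.6
  expect_equal(nrow(out), 1)
  expect_equal(out$x, 100)
  expect_equal(out$conf, 1)
  expect_equal(out$source, "fused")
  # IOU below threshold: falls back to solo rules, both fail here
  m2 <- mot(5, x = 112)                                  # IOU = 8/32 = 0.25
  expect_equal(nrow(fuse(app(0.4, 100), m2, cfg)), 0)
  # ... but solo rules still apply individually on a failed pair
  expect_equal(nrow(fuse(app(0.8, 100), mot(40, 112), cfg)), 2)
  # appearance below the 0.3 floor is discarded entirely
  expect_equal(nrow(fuse(app(0.2, 100), NULL, cfg)), 0)
})

test_that("fuse agrees with a truth-table evaluator on a threshold grid", {
  cfg <- fusion_config()
  grid <- expand.grid(conf = c(0.2, 0.3, 0.5, 0.7, 0.71, 0.9),
                      count = c(1, 29, 30, 31, 60),
                      dist = c(0, 10, 19.5, 25),
                      iou_case = c("high", "low"))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    # geometry: motion box shifted horizontally by dist so pair IOU is
    # controlled by box size: 40-wide boxes at dist <= 20 keep IOU > 0.5
    # ("high"); 12-wide boxes drop IOU below 0.5 at dist > 4 ("low")
    wbox <- if (g$iou_case == "high") 60 else 12
    a <- bounding_boxes(0, 100, 100, wbox, wbox, conf = g$conf)
    m <- bounding_boxes(0, 100 + g$dist, 100, wbox, wbox, conf = 1,
                        source = "motion")
    m$consecutive_frames <- g$count
    out <- fuse(a, m, cfg)
    pair_iou <- iou(a, m)
    truth <- fusion_truth_table(g$conf, g$count, g$dist, pair_iou, cfg)
    expect_equal(nrow(out), sum(truth$app_kept, truth$motion_kept),
                 info = paste(unlist(g), collapse = "/"))
  }
})

test_that("fusion output is invariant to input order and monotone in the solo threshold", {
  set.seed(21)
  app <- bounding_boxes(rep(0, 6), x = seq(0, 500, by = 100),
                        y = 50, w = 20, h = 20,
                        conf = runif(6))
  mot <- bounding_boxes(rep(0, 4), x = seq(0, 300, by = 100) + 3,
                        y = 52, w = 20, h = 20, conf = 1, source = "motion")
  mot$consecutive_frames <- c(40, 2, 31, 12)
  cfg <- fusion_config()
  out1 <- fuse(app, mot, cfg)
  perm <- fuse(app[sample(6), ], mot[sample(4), ], cfg)
  expect_setequal(round(out1$x, 9), round(perm$x, 9))

  for (thr in c(0.5, 0.7, 0.9, 0.99)) {
    cfg2 <- fusion_config(appearance_conf_solo = thr)
    expect_lte(nrow(fuse(app, mot, cfg2)),
               nrow(fuse(app, mot, fusion_config(appearance_conf_solo = 0.31))))
  }
})

test_that("fuse_sequence confirms persistent motion only after the threshold", {
  cfg <- fusion_config(motion_persistence_frames = 30)
  n <- 40
  mot <- bounding_boxes(frame = 0:(n - 1), x = 100, y = 100, w = 15, h = 15,
                        conf = 1, source = "motion")
  fused <- fuse_sequence(empty_boxes(), mot, n, cfg)
  # counts reach 31 at frame index 30 (0-based): confirmed from then on
  expect_equal(sort(unique(fused$frame)), 30:39)
})
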