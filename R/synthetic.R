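# Ground-truthed synthetic stereo thermal scenes. A handful of warm,
# blob-like targets fly inside a cubic observation box with abrupt speed
# and direction changes and occasional perching, and are rendered into two
# rectified parallel cameras as anisotropic Gaussian blobs (elongated along
# the image velocity to emulate motion blur) over a warm-plate background
# gradient with additive sensor noise.

#' Synthetic scene configuration
#'
#' Defaults describe the observation conditions the package targets: a
#' 0.30 m cube holding 5 targets, filmed at 30 fps and 640x480 by a
#' parallel rig whose frustum covers the whole cube, with the box center
#' 0.50 m from the left camera so that unblurred blob silhouettes span the
#' 150-550 px^2 operating band across the full depth range.
#'
#' @param box_side cube side in meters.
#' @param n_targets number of targets.
#' @param frame_rate frames per second.
#' @param duration_s scene length in seconds.
#' @param speed_range flight speed range in m/s.
#' @param turn_hazard rate (per second) of abrupt speed/direction changes.
#' @param perch_hazard rate (per second) of entering a stationary phase.
#' @param perch_duration_s range of stationary-phase lengths in seconds.
#' @param blob_sigma_m physical Gaussian radius of a target's warm blob (m).
#' @param blob_intensity peak blob intensity above background (levels).
#' @param noise_sd additive sensor noise standard deviation (levels).
#' @param blur_gain motion-blur elongation per px/frame of image speed.
#' @param box_center_z distance from the left camera to the box center (m).
#' @param rng_seed integer seed; every stochastic step derives from it.
#' @return list of class `scene_config`.
#' @export
scene_config <- function(box_side = 0.30, n_targets = 5, frame_rate = 30,
                         duration_s = 10, speed_range = c(0.05, 0.2),
                         turn_hazard = 0.5, perch_hazard = 0.1,
                         perch_duration_s = c(1, 3), blob_sigma_m = 0.007,
                         blob_intensity = 80, noise_sd = 3, blur_gain = 0.5,
                         box_center_z = 0.50, rng_seed = 1L) {
  stopifnot(n_targets >= 1, box_side > 0, frame_rate > 0, duration_s > 0,
            all(speed_range >= 0), turn_hazard >= 0, perch_hazard >= 0,
            noise_sd >= 0, blur_gain >= 0)
  structure(list(box_side = box_side, n_targets = as.integer(n_targets),
                 frame_rate = frame_rate, duration_s = duration_s,
                 speed_range = speed_range, turn_hazard = turn_hazard,
                 perch_hazard = perch_hazard,
                 perch_duration_s = perch_duration_s,
                 blob_sigma_m = blob_sigma_m,
                 blob_intensity = blob_intensity, noise_sd = noise_sd,
                 blur_gain = blur_gain, box_center_z = box_center_z,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_config")
}

#' Default rig for the synthetic scenes
#'
#' Focal length 550 px and baseline 0.08 m place the whole 0.30 m cube
#' inside both camera frusta at the default working distance while keeping
#' disparities (and hence depth resolution) large.
#'
#' @param cfg a [scene_config()] (used for the box placement).
#' @return a [camera_rig()].
#' @export
default_rig <- function(cfg = scene_config()) {
  camera_rig(f = 550, B = 0.08, width = 640L, height = 480L)
}

box_origin <- function(cfg, rig) {
  # box center sits midway between the cameras laterally
  c(rig$B / 2, 0, cfg$box_center_z)
}

random_direction <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

#' Simulate 3D flight paths
#'
#' Piecewise constant-velocity flight with Poisson-timed abrupt speed and
#' direction changes, Poisson-timed perch (stationary) intervals, and
#' reflection at the box walls. Deterministic given `rng_seed`.
#'
#' @param cfg a [scene_config()].
#' @param rig a [camera_rig()] (box placement in the camera frame).
#' @return list with `positions` (array frame x target x 3, meters,
#'   left-camera frame), `state` (frame x target character matrix,
#'   `"flying"`/`"perched"`), and `n_frames`.
#' @export
simulate_paths <- function(cfg = scene_config(), rig = default_rig(cfg)) {
  set.seed(cfg$rng_seed)
  n_frames <- round(cfg$duration_s * cfg$frame_rate)
  dt <- 1 / cfg$frame_rate
  half <- cfg$box_side / 2
  orig <- box_origin(cfg, rig)
  margin <- 0.02

  pos <- array(NA_real_, c(n_frames, cfg$n_targets, 3))
  state <- matrix("flying", n_frames, cfg$n_targets)

  for (k in seq_len(cfg$n_targets)) {
    p <- runif(3, -half + margin, half - margin)
    speed <- runif(1, cfg$speed_range[1], cfg$speed_range[2])
    vel <- random_direction() * speed
    perch_left <- 0
    for (t in seq_len(n_frames)) {
      if (perch_left > 0) {
        perch_left <- perch_left - 1
        state[t, k] <- "perched"
      } else {
        if (runif(1) < cfg$perch_hazard * dt) {
          perch_left <- round(runif(1, cfg$perch_duration_s[1],
                                    cfg$perch_duration_s[2]) * cfg$frame_rate)
          state[t, k] <- "perched"
        } else {
          if (runif(1) < cfg$turn_hazard * dt || all(vel == 0)) {
            speed <- runif(1, cfg$speed_range[1], cfg$speed_range[2])
            vel <- random_direction() * speed
          }
          p <- p + vel * dt
          # reflect at the walls
          for (ax in 1:3) {
            lo <- -half + margin; hi <- half - margin
            if (p[ax] < lo) { p[ax] <- 2 * lo - p[ax]; vel[ax] <- -vel[ax] }
            if (p[ax] > hi) { p[ax] <- 2 * hi - p[ax]; vel[ax] <- -vel[ax] }
          }
        }
      }
      pos[t, k, ] <- orig + p
    }
  }
  list(positions = pos, state = state, n_frames = n_frames)
}

scene_background <- function(cfg, rig) {
  # warm-plate gradient: warmer (brighter) toward the bottom of the frame,
  # plus a frozen spatial texture the background model can learn
  y <- seq(0, 1, length.out = rig$height)
  base <- matrix(rep(90 + 50 * y, rig$width), rig$height, rig$width)
  base + matrix(rnorm(rig$height * rig$width, 0, 1.5), rig$height, rig$width)
}

#' Render target-free background frames
#'
#' Frames containing only the background gradient, its frozen texture and
#' fresh sensor noise; useful for settling the background model before a
#' sequence (see [detect_motion()]).
#'
#' @param cfg a [scene_config()].
#' @param rig a [camera_rig()].
#' @param n number of frames.
#' @param base optional precomputed background (from the render result).
#' @return list of grayscale matrices.
#' @export
render_background <- function(cfg, rig, n, base = NULL) {
  if (is.null(base)) base <- scene_background(cfg, rig)
  lapply(seq_len(n), function(i)
    base + matrix(rnorm(length(base), 0, cfg$noise_sd),
                  nrow(base), ncol(base)))
}

render_blob <- function(img, uc, vc, s_along, s_cross, dir_uv, amp) {
  ext <- ceiling(3.2 * max(s_along, s_cross))
  x1 <- max(1, floor(uc) - ext); x2 <- min(ncol(img), ceiling(uc) + ext)
  y1 <- max(1, floor(vc) - ext); y2 <- min(nrow(img), ceiling(vc) + ext)
  if (x2 < x1 || y2 < y1) return(img)
  xs <- (x1:x2) - 1 - uc     # pixel centers, 0-based
  ys <- (y1:y2) - 1 - vc
  du <- outer(rep(1, length(ys)), xs)
  dv <- outer(ys, rep(1, length(xs)))
  a <- du * dir_uv[1] + dv * dir_uv[2]
  b <- -du * dir_uv[2] + dv * dir_uv[1]
  g <- amp * exp(-0.5 * ((a / s_along)^2 + (b / s_cross)^2))
  img[y1:y2, x1:x2] <- img[y1:y2, x1:x2] + g
  img
}

#' Render a stereo thermal scene
#'
#' Projects simulated paths into both cameras and renders each target as an
#' anisotropic Gaussian blob elongated along its image-plane velocity
#' (motion blur), over the warm background with additive sensor noise.
#' Ground-truth 2D boxes are the blobs' above-half-maximum extents centered
#' on the exact pinhole projections.
#'
#' @param paths result of [simulate_paths()].
#' @param rig a [camera_rig()].
#' @param cfg a [scene_config()].
#' @return list with `left`, `right` (lists of frames), `gt2d` (list with
#'   per-camera bounding-box data frames, `id` = target), `gt3d` (data
#'   frame `track_id, frame, Xc, Yc, Zc`), and `background` (noise-free
#'   base image).
#' @export
render_stereo <- function(paths, rig, cfg = scene_config()) {
  set.seed(cfg$rng_seed + 7919L)   # rendering noise, decoupled from paths
  n_frames <- paths$n_frames
  nt <- dim(paths$positions)[2]
  base <- scene_background(cfg, rig)
  left <- vector("list", n_frames)
  right <- vector("list", n_frames)
  gt <- list(left = vector("list", n_frames), right = vector("list", n_frames))

  for (t in seq_len(n_frames)) {
    fl <- base + matrix(rnorm(length(base), 0, cfg$noise_sd),
                        nrow(base), ncol(base))
    fr <- base + matrix(rnorm(length(base), 0, cfg$noise_sd),
                        nrow(base), ncol(base))
    rows <- list(left = NULL, right = NULL)
    for (k in seq_len(nt)) {
      P <- paths$positions[t, k, , drop = TRUE]
      if (t > 1) {
        Pprev <- paths$positions[t - 1, k, , drop = TRUE]
      } else Pprev <- P
      for (cam in c("left", "right")) {
        uv <- project_points(matrix(P, 1), rig, cam)
        uvp <- project_points(matrix(Pprev, 1), rig, cam)
        vel_uv <- uv - uvp
        speed_px <- sqrt(sum(vel_uv^2))
        dir_uv <- if (speed_px > 1e-9) vel_uv / speed_px else c(1, 0)
        s_px <- rig$f * cfg$blob_sigma_m / P[3]
        s_along <- s_px + cfg$blur_gain * speed_px
        s_cross <- s_px
        if (uv[1] < -40 || uv[1] > rig$width + 40 ||
            uv[2] < -40 || uv[2] > rig$height + 40) {
          warning("target ", k, " outside frustum at frame ", t, "; clipped")
          next
        }
        img <- if (cam == "left") fl else fr
        img <- render_blob(img, uv[1], uv[2], s_along, s_cross, dir_uv,
                           cfg$blob_intensity)
        if (cam == "left") fl <- img else fr <- img
        # half-maximum extent of the (possibly elongated) blob, centered on
        # the exact projection
        hw <- 1.1774 * sqrt(s_along^2 * dir_uv[1]^2 + s_cross^2 * dir_uv[2]^2)
        hh <- 1.1774 * sqrt(s_along^2 * dir_uv[2]^2 + s_cross^2 * dir_uv[1]^2)
        rows[[cam]] <- rbind(rows[[cam]],
                             data.frame(frame = t - 1L, id = k,
                                        x = uv[1] - hw, y = uv[2] - hh,
                                        w = 2 * hw, h = 2 * hh, conf = 1,
                                        source = "appearance",
                                        stringsAsFactors = FALSE))
      }
    }
    fl[fl < 0] <- 0; fl[fl > 255] <- 255
    fr[fr < 0] <- 0; fr[fr > 255] <- 255
    left[[t]] <- fl; right[[t]] <- fr
    gt$left[[t]] <- rows$left
    gt$right[[t]] <- rows$right
  }

  gt2d <- list(left = do.call(rbind, gt$left), right = do.call(rbind, gt$right))
  gt3d <- do.call(rbind, lapply(seq_len(nt), function(k)
    data.frame(track_id = k, frame = seq_len(n_frames) - 1L,
               Xc = paths$positions[, k, 1], Yc = paths$positions[, k, 2],
               Zc = paths$positions[, k, 3])))
  list(left = left, right = right, gt2d = gt2d, gt3d = gt3d,
       background = base)
}

#' Export scene ground truth
#'
#' Writes per-camera MOT16 ground-truth files and the 3D path CSV under a
#' scene directory, re-readable via the package's readers.
#'
#' @param scene result of [render_stereo()].
#' @param out_dir output directory (created if needed).
#' @return invisible vector of file paths.
#' @export
export_ground_truth <- function(scene, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(gt_left = file.path(out_dir, "gt_left.txt"),
             gt_right = file.path(out_dir, "gt_right.txt"),
             gt3d = file.path(out_dir, "gt_3d.csv"))
  gl <- scene$gt2d$left
  gr <- scene$gt2d$right
  if (is.null(gl)) gl <- empty_boxes()
  if (is.null(gr)) gr <- empty_boxes()
  write_mot16(gl, paths["gt_left"])
  write_mot16(gr, paths["gt_right"])
  g3 <- scene$gt3d
  if (is.null(g3)) g3 <- data.frame(track_id = integer(), frame = integer(),
                                    Xc = numeric(), Yc = numeric(),
                                    Zc = numeric())
  write_trajectory3d(g3, paths["gt3d"])
  invisible(paths)
}

#' Intensity-threshold stand-in appearance detector
#'
#' A deliberately simple appearance detector for synthetic end-to-end
#' runs, standing where a trained network's detections would enter through
#' the detection-file interface: pixels above a threshold midway up the
#' blob profile are grouped into 8-connected components, size-filtered,
#' and returned as appearance boxes. Confidence grows with the component's
#' peak intensity above the threshold.
#'
#' @param frames list of grayscale matrices.
#' @param cfg a [scene_config()] (threshold derives from its intensity
#'   model).
#' @param background noise-free background image (from the render result).
#' @param area_range components outside this pixel-count range are dropped.
#' @return bounding-box data frame with source `"appearance"`.
#' @export
standin_detector <- function(frames, cfg, background,
                             area_range = c(40, 4000)) {
  thr_img <- background + cfg$blob_intensity / 2
  out <- vector("list", length(frames))
  for (t in seq_along(frames)) {
    mask <- matrix(as.integer(frames[[t]] > thr_img),
                   nrow(background), ncol(background))
    lab <- .label_components(mask, 8L)
    st <- lab$stats
    keep <- st$count >= area_range[1] & st$count <= area_range[2]
    st <- st[keep, , drop = FALSE]
    if (nrow(st) == 0) next
    conf <- numeric(nrow(st))
    excess <- frames[[t]] - thr_img
    for (i in seq_len(nrow(st))) {
      sel <- lab$labels == st$label[i]
      conf[i] <- min(0.99, 0.5 + 0.5 * max(excess[sel]) /
                             (cfg$blob_intensity / 2))
    }
    out[[t]] <- bounding_boxes(frame = rep(t - 1L, nrow(st)), x = st$xmin,
                               y = st$ymin, w = st$xmax - st$xmin + 1,
                               h = st$ymax - st$ymin + 1,
                               conf = pmax(conf, 0.05), source = "appearance")
  }
  res <- do.call(rbind, out)
  if (is.null(res)) empty_boxes() else res
}

#' Corrupt a ground-truth stream into a stressed detection stream
#'
#' Turns exact per-frame ground-truth boxes into a realistic stressed
#' detector output: each box is dropped with probability `dropout`, jittered
#' with Gaussian center/size noise, and spurious boxes appear at Poisson
#' rate `spurious_rate` per frame at random positions.
#'
#' @param gt ground-truth bounding-box data frame.
#' @param n_frames frames covered.
#' @param dropout per-box miss probability.
#' @param jitter_px center jitter standard deviation.
#' @param spurious_rate expected spurious boxes per frame.
#' @param width,height image bounds for spurious boxes.
#' @param seed RNG seed.
#' @return bounding-box data frame (id = -1).
#' @export
corrupt_detections <- function(gt, n_frames, dropout = 0.1, jitter_px = 1,
                               spurious_rate = 0.2, width = 640,
                               height = 480, seed = 1L) {
  set.seed(seed)
  keep <- runif(nrow(gt)) > dropout
  det <- gt[keep, , drop = FALSE]
  det$x <- det$x + rnorm(nrow(det), 0, jitter_px)
  det$y <- det$y + rnorm(nrow(det), 0, jitter_px)
  det$w <- pmax(2, det$w * exp(rnorm(nrow(det), 0, 0.05)))
  det$h <- pmax(2, det$h * exp(rnorm(nrow(det), 0, 0.05)))
  det$id <- -1L
  det$conf <- 0.9
  n_sp <- stats::rpois(n_frames, spurious_rate)
  sp_frames <- rep(seq_len(n_frames) - 1L, n_sp)
  if (length(sp_frames)) {
    mw <- stats::median(gt$w)
    sp <- bounding_boxes(frame = sp_frames,
                         x = runif(length(sp_frames), 0, width - mw),
                         y = runif(length(sp_frames), 0, height - mw),
                         w = mw * exp(rnorm(length(sp_frames), 0, 0.1)),
                         h = mw * exp(rnorm(length(sp_frames), 0, 0.1)),
                         conf = 0.9, source = "appearance")
    det <- rbind(det[, names(sp)], sp)
  } else det <- det[, names(empty_boxes())]
  det <- det[order(det$frame), , drop = FALSE]
  rownames(det) <- NULL
  det
}
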