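# End-to-end composition: motion detection -> fusion -> tracking per
# camera -> stereo pairing -> 3D reconstruction, plus scoring against
# ground truth when available.

#' Run the full pipeline on a rendered stereo scene
#'
#' For each camera: motion detection (with background warm-up frames),
#' appearance detection via the stand-in detector (or supplied appearance
#' boxes), rule-based fusion, and population-aware tracking. The two
#' cameras' tracks are then paired and triangulated into 3D trajectories.
#'
#' @param scene result of [render_stereo()].
#' @param rig the [camera_rig()] used to render.
#' @param cfg a [scene_config()] (intensity model for the stand-in
#'   detector).
#' @param seg_cfg a [motion_seg_config()].
#' @param fuse_cfg a [fusion_config()].
#' @param trk_cfg a [tracker_config()]; `n_expected` defaults to the
#'   scene's target count.
#' @param appearance optional list with `left`/`right` appearance boxes to
#'   use instead of the stand-in detector.
#' @param warmup background frames prepended to settle the background
#'   model.
#' @return list with per-camera `detections` (fused), `records` (track
#'   records), and `trajectories` (3D data frame).
#' @export
run_pipeline <- function(scene, rig, cfg, seg_cfg = motion_seg_config(),
                         fuse_cfg = fusion_config(),
                         trk_cfg = NULL, appearance = NULL, warmup = 40) {
  if (is.null(trk_cfg))
    trk_cfg <- tracker_config(n_expected = max(scene$gt2d$left$id))
  n_frames <- length(scene$left)
  warm <- render_background(cfg, rig, warmup, base = scene$background)
  out <- list()
  for (cam in c("left", "right")) {
    frames <- scene[[cam]]
    mot <- detect_motion(frames, seg_cfg, warmup_frames = warm)
    app <- if (!is.null(appearance)) appearance[[cam]]
           else standin_detector(frames, cfg, scene$background)
    fused <- fuse_sequence(app, mot$boxes, n_frames, fuse_cfg)
    tracks <- track_sequence(fused, n_frames, trk_cfg)
    out[[cam]] <- list(motion = mot$boxes, appearance = app,
                       detections = fused,
                       records = tracks_to_records(tracks))
  }
  traj <- reconstruct_all(out$left$records, out$right$records, rig)
  list(left = out$left, right = out$right, trajectories = traj)
}

#' Score reconstructed trajectories against 3D ground truth
#'
#' Estimated tracks are assigned to ground-truth targets by optimal
#' assignment on mean 3D distance over common frames; per-frame Euclidean
#' errors are pooled over all assigned pairs.
#'
#' @param traj reconstructed trajectories (`track_id, frame, Xc, Yc, Zc`).
#' @param gt3d ground-truth 3D paths in the same layout.
#' @return list with `mean`, `median`, `max` error (meters), `n` pooled
#'   frames, and the per-pair table `pairs`.
#' @export
score_trajectories <- function(traj, gt3d) {
  tids <- sort(unique(traj$track_id)); gids <- sort(unique(gt3d$track_id))
  if (length(tids) == 0) stop("no reconstructed trajectories to score")
  cost <- matrix(Inf, length(tids), length(gids))
  for (i in seq_along(tids)) {
    ti <- traj[traj$track_id == tids[i], , drop = FALSE]
    for (j in seq_along(gids)) {
      gj <- gt3d[gt3d$track_id == gids[j], , drop = FALSE]
      common <- intersect(ti$frame, gj$frame)
      if (length(common) == 0) next
      a <- as.matrix(ti[match(common, ti$frame), c("Xc", "Yc", "Zc")])
      b <- as.matrix(gj[match(common, gj$frame), c("Xc", "Yc", "Zc")])
      cost[i, j] <- mean(sqrt(rowSums((a - b)^2)))
    }
  }
  assign <- solve_assignment(cost)
  errs <- numeric(); pairs <- NULL
  for (i in seq_along(tids)) {
    if (is.na(assign[i]) || !is.finite(cost[i, assign[i]])) next
    ti <- traj[traj$track_id == tids[i], , drop = FALSE]
    gj <- gt3d[gt3d$track_id == gids[assign[i]], , drop = FALSE]
    common <- intersect(ti$frame, gj$frame)
    a <- as.matrix(ti[match(common, ti$frame), c("Xc", "Yc", "Zc")])
    b <- as.matrix(gj[match(common, gj$frame), c("Xc", "Yc", "Zc")])
    e <- sqrt(rowSums((a - b)^2))
    errs <- c(errs, e)
    pairs <- rbind(pairs, data.frame(track_id = tids[i],
                                     gt_id = gids[assign[i]],
                                     n = length(e), mean = mean(e)))
  }
  if (length(errs) == 0) stop("no trajectory could be paired with ground truth")
  list(mean = mean(errs), median = stats::median(errs), max = max(errs),
       n = length(errs), pairs = pairs)
}
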