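# Appearance/motion detection fusion. An appearance detector (e.g. a
# trained single-stage CNN) proposes boxes with confidences; the motion
# chain proposes boxes for moving targets. Three confirmation rules decide
# which boxes are true targets:
#   1. an appearance box with confidence above the solo threshold;
#   2. a motion candidate seen in more consecutive frames than the
#      persistence threshold;
#   3. an appearance/motion pair whose centers lie within the gate and
#      whose boxes overlap above the IOU threshold.

#' Fusion configuration
#'
#' All comparisons are strict (`>`), matching the rule statements. The
#' appearance confidence floor is a list-entry filter applied before the
#' rules: boxes below it are discarded as detector noise.
#'
#' @param appearance_conf_floor minimum confidence for an appearance box to
#'   enter fusion at all.
#' @param appearance_conf_solo confidence above which an appearance box is
#'   confirmed on its own (rule 1).
#' @param motion_persistence_frames consecutive-frame count above which a
#'   motion candidate is confirmed on its own (rule 2).
#' @param center_gate_px center-distance gate for pairing appearance and
#'   motion boxes (rule 3).
#' @param iou_confirm IOU above which a gated pair is confirmed (rule 3).
#' @param persistence_link_px center-distance gate for frame-to-frame
#'   linking of motion candidates.
#' @return list of class `fusion_config`.
#' @export
fusion_config <- function(appearance_conf_floor = 0.3,
                          appearance_conf_solo = 0.7,
                          motion_persistence_frames = 30,
                          center_gate_px = 20, iou_confirm = 0.5,
                          persistence_link_px = 20) {
  stopifnot(appearance_conf_floor >= 0,
            appearance_conf_floor < appearance_conf_solo,
            appearance_conf_solo <= 1, motion_persistence_frames > 0,
            center_gate_px > 0, iou_confirm > 0, persistence_link_px > 0)
  structure(list(appearance_conf_floor = appearance_conf_floor,
                 appearance_conf_solo = appearance_conf_solo,
                 motion_persistence_frames = motion_persistence_frames,
                 center_gate_px = center_gate_px, iou_confirm = iou_confirm,
                 persistence_link_px = persistence_link_px),
            class = "fusion_config")
}

# Greedy mutual-nearest pairing of two center sets within a gate.
# Returns a two-column matrix of (i, j) index pairs. Ties broken by lower
# row index, then lower column index.
greedy_center_pairs <- function(ca, cb, gate) {
  if (nrow(ca) == 0 || nrow(cb) == 0) return(cbind(i = integer(), j = integer()))
  d <- sqrt(outer(ca[, 1], cb[, 1], "-")^2 + outer(ca[, 2], cb[, 2], "-")^2)
  ord <- order(d, row(d), col(d))
  usedi <- logical(nrow(ca)); usedj <- logical(nrow(cb))
  out <- NULL
  for (k in ord) {
    if (d[k] > gate) break
    i <- row(d)[k]; j <- col(d)[k]
    if (usedi[i] || usedj[j]) next
    usedi[i] <- TRUE; usedj[j] <- TRUE
    out <- rbind(out, c(i, j))
  }
  if (is.null(out)) cbind(i = integer(), j = integer()) else
    matrix(out, ncol = 2, dimnames = list(NULL, c("i", "j")))
}

#' Update the per-frame motion-candidate set
#'
#' Motion candidates carry a consecutive-frame appearance count. Call once
#' per frame, in frame order, with that frame's motion boxes: a motion box
#' whose center lies within `persistence_link_px` of an existing candidate
#' (greedy nearest pairing) inherits the candidate and increments its count;
#' unlinked boxes start new candidates at count 1; candidates with no linked
#' box this frame are dropped.
#'
#' @param candidates data frame from a previous call (or NULL/empty).
#' @param motion_boxes this frame's motion boxes.
#' @param cfg a [fusion_config()].
#' @return data frame with the box columns plus `consecutive_frames`.
#' @export
update_motion_candidates <- function(candidates, motion_boxes,
                                     cfg = fusion_config()) {
  if (is.null(candidates) || nrow(candidates) == 0) {
    out <- motion_boxes
    out$consecutive_frames <- rep(1L, nrow(motion_boxes))
    return(out)
  }
  if (nrow(motion_boxes) == 0) {
    out <- candidates[0, , drop = FALSE]
    return(out)
  }
  pairs <- greedy_center_pairs(box_centers(motion_boxes),
                               box_centers(candidates),
                               cfg$persistence_link_px)
  counts <- rep(1L, nrow(motion_boxes))
  if (nrow(pairs) > 0)
    counts[pairs[, "i"]] <- candidates$consecutive_frames[pairs[, "j"]] + 1L
  out <- motion_boxes
  out$consecutive_frames <- counts
  out
}

#' Fuse appearance and motion detections for one frame
#'
#' Applies the three confirmation rules. Appearance boxes below the
#' confidence floor are discarded first. Each surviving appearance box is
#' paired with at most one motion candidate by greedy nearest-center
#' pairing within `center_gate_px`. A gated pair with IOU above
#' `iou_confirm` is confirmed and emitted with the appearance geometry and
#' the pair's maximum confidence; a failed pair falls back to the solo rules
#' for each member. Solo appearance boxes need confidence above
#' `appearance_conf_solo`; solo motion candidates need a consecutive-frame
#' count above `motion_persistence_frames`.
#'
#' @param appearance appearance boxes for one frame.
#' @param candidates motion-candidate data frame from
#'   [update_motion_candidates()] for the same frame.
#' @param cfg a [fusion_config()].
#' @return bounding-box data frame with source `"fused"`.
#' @export
fuse <- function(appearance, candidates, cfg = fusion_config()) {
  if (is.null(candidates)) candidates <- empty_boxes()
  app <- appearance[appearance$conf >= cfg$appearance_conf_floor, , drop = FALSE]
  napp <- nrow(app); ncand <- nrow(candidates)
  keep_app <- logical(napp)
  conf_app <- if (napp) app$conf else numeric()
  cand_paired_ok <- logical(ncand)

  pairs <- greedy_center_pairs(
    if (napp) box_centers(app) else matrix(0, 0, 2),
    if (ncand) box_centers(candidates) else matrix(0, 0, 2),
    cfg$center_gate_px)

  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, "i"]; j <- pairs[k, "j"]
      ov <- iou(app[i, , drop = FALSE], candidates[j, , drop = FALSE])
      if (ov > cfg$iou_confirm) {          # rule 3
        keep_app[i] <- TRUE
        conf_app[i] <- max(app$conf[i], candidates$conf[j])
        cand_paired_ok[j] <- TRUE
      }
    }
  }
  keep_app <- keep_app | (if (napp) app$conf > cfg$appearance_conf_solo
                          else logical())                       # rule 1
  keep_cand <- if (ncand)
    !cand_paired_ok &
      candidates$consecutive_frames > cfg$motion_persistence_frames  # rule 2
  else logical()

  out_a <- app[keep_app, , drop = FALSE]
  if (nrow(out_a)) { out_a$conf <- conf_app[keep_app]; out_a$source <- "fused" }
  out_m <- candidates[keep_cand, intersect(names(candidates), names(empty_boxes())),
                      drop = FALSE]
  if (nrow(out_m)) out_m$source <- "fused"
  out <- rbind(out_a[, names(empty_boxes())[names(empty_boxes()) %in% names(out_a)],
                     drop = FALSE],
               out_m)
  if (is.null(out) || nrow(out) == 0) return(empty_boxes())
  rownames(out) <- NULL
  out
}

#' Fuse a whole detection stream
#'
#' Drives [update_motion_candidates()] and [fuse()] over frames `0..n-1`.
#'
#' @param appearance bounding-box data frame of appearance detections.
#' @param motion bounding-box data frame of motion detections.
#' @param n_frames number of frames to process.
#' @param cfg a [fusion_config()].
#' @return bounding-box data frame of fused detections (source `"fused"`).
#' @export
fuse_sequence <- function(appearance, motion, n_frames, cfg = fusion_config()) {
  candidates <- NULL
  out <- vector("list", n_frames)
  for (t in seq_len(n_frames) - 1L) {
    mb <- motion[motion$frame == t, , drop = FALSE]
    ab <- appearance[appearance$frame == t, , drop = FALSE]
    candidates <- update_motion_candidates(candidates, mb, cfg)
    ft <- fuse(ab, candidates, cfg)
    if (nrow(ft)) ft$frame <- t
    out[[t + 1L]] <- ft
  }
  res <- do.call(rbind, out)
  if (is.null(res)) empty_boxes() else res
}
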