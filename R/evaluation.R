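# Detection metrics (precision, recall, F1, average precision) and
# CLEAR-MOT tracking metrics (MOTA, MOTP, identity switches) against
# MOT16-format ground truth.

#' Precision, recall and F1 from match counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`,
#' `F1 = 2 P R / (P + R)`. Degenerate denominators yield 0 with a warning.
#'
#' @param tp,fp,fn non-negative counts.
#' @return list with `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else { warning("TP + FP = 0; precision set to 0"); 0 }
  r <- if (tp + fn > 0) tp / (tp + fn) else { warning("TP + FN = 0; recall set to 0"); 0 }
  f1 <- f1_score(p, r)
  list(precision = p, recall = r, f1 = f1)
}

#' F1 score from precision and recall
#'
#' @param p,r precision and recall in `[0, 1]`.
#' @return harmonic mean `2 P R / (P + R)`; 0 when `P + R = 0`.
#' @export
f1_score <- function(p, r) ifelse(p + r > 0, 2 * p * r / (p + r), 0)

#' Average precision of scored detections
#'
#' Area under the precision-envelope vs recall curve with all-point
#' interpolation. Detections are ranked by descending confidence and
#' matched greedily to unmatched ground-truth boxes of the same frame at
#' IOU at or above `iou_match` (best-IOU first), one match per truth box.
#'
#' @param detections bounding-box data frame with confidences.
#' @param gt ground-truth bounding-box data frame.
#' @param iou_match IOU matching threshold.
#' @return average precision in `[0, 1]`.
#' @export
average_precision <- function(detections, gt, iou_match = 0.5) {
  if (nrow(gt) == 0) stop("average precision is undefined with empty ground truth")
  if (nrow(detections) == 0) return(0)
  ord <- order(-detections$conf, detections$frame)
  det <- detections[ord, , drop = FALSE]
  gt_used <- rep(FALSE, nrow(gt))
  tp <- integer(nrow(det))
  for (k in seq_len(nrow(det))) {
    cand <- which(gt$frame == det$frame[k] & !gt_used)
    if (length(cand) == 0) next
    ov <- iou(det[k, , drop = FALSE], gt[cand, , drop = FALSE])
    best <- which.max(ov)
    if (ov[best] >= iou_match) {
      tp[k] <- 1L
      gt_used[cand[best]] <- TRUE
    }
  }
  cum_tp <- cumsum(tp)
  prec <- cum_tp / seq_along(tp)
  rec <- cum_tp / nrow(gt)
  # precision envelope (running maximum from the right), integrated over
  # the recall increments
  env <- rev(cummax(rev(prec)))
  dr <- diff(c(0, rec))
  sum(env * dr)
}

#' CLEAR-MOT tracking metrics
#'
#' Frame-wise correspondence between ground truth and hypotheses:
#' correspondences from the previous frame are kept while both boxes exist
#' and remain within the gate; the remainder are matched by optimal
#' assignment on center distance (or `1 - IOU`). An identity switch is
#' counted when a truth target is matched to a different hypothesis id
#' than its last match. `MOTA = 1 - (FN + FP + IDS) / GT` (can be
#' negative); MOTP is reported both as the raw mean center distance of
#' matched pairs in pixels and normalised by the gate.
#'
#' @param gt,hyp MOT-style bounding-box data frames (columns incl. `id`).
#' @param gate matching gate: maximum center distance in px
#'   (`gate_type = "center"`) or minimum IOU (`gate_type = "iou"`).
#' @param gate_type `"center"` or `"iou"`.
#' @return list with `mota`, `motp_px`, `motp_norm`, `ids`, `counts`
#'   (totals), and `frames` (per-frame table).
#' @export
clear_mot <- function(gt, hyp, gate = 50, gate_type = c("center", "iou")) {
  gate_type <- match.arg(gate_type)
  if (anyDuplicated(gt[, c("frame", "id")]))
    stop("duplicate (frame, id) rows in ground truth")
  if (anyDuplicated(hyp[, c("frame", "id")]))
    stop("duplicate (frame, id) rows in hypotheses")
  frames <- sort(unique(c(gt$frame, hyp$frame)))
  last_match <- list()   # gt id -> hyp id of last correspondence
  corr <- list()         # current correspondences, gt id -> hyp id
  tot <- list(fn = 0L, fp = 0L, ids = 0L, gt = 0L, c = 0L, dist = 0)
  per_frame <- vector("list", length(frames))

  pair_cost <- function(g, h) {
    if (gate_type == "center") {
      cg <- box_centers(g); chp <- box_centers(h)
      D <- sqrt(outer(cg[, 1], chp[, 1], "-")^2 + outer(cg[, 2], chp[, 2], "-")^2)
      D[D > gate] <- Inf
      D
    } else {
      M <- iou_matrix(g, h)
      D <- 1 - M
      D[M < gate] <- Inf
      D
    }
  }

  for (fi in seq_along(frames)) {
    t <- frames[fi]
    g <- gt[gt$frame == t, , drop = FALSE]
    h <- hyp[hyp$frame == t, , drop = FALSE]
    D <- pair_cost(g, h)
    new_corr <- list()
    used_g <- logical(nrow(g)); used_h <- logical(nrow(h))
    dists <- numeric()

    # keep surviving correspondences
    for (gid in names(corr)) {
      gi <- match(as.integer(gid), g$id)
      hi <- match(corr[[gid]], h$id)
      if (is.na(gi) || is.na(hi)) next
      if (is.finite(D[gi, hi])) {
        new_corr[[gid]] <- corr[[gid]]
        used_g[gi] <- TRUE; used_h[hi] <- TRUE
        dists <- c(dists, D[gi, hi])
      }
    }
    # optimal assignment on the remainder
    rg <- which(!used_g); rh <- which(!used_h)
    if (length(rg) && length(rh)) {
      a <- solve_assignment(D[rg, rh, drop = FALSE])
      for (i in seq_along(rg)) {
        if (is.na(a[i]) || !is.finite(D[rg[i], rh[a[i]]])) next
        gid <- as.character(g$id[rg[i]])
        new_corr[[gid]] <- h$id[rh[a[i]]]
        used_g[rg[i]] <- TRUE; used_h[rh[a[i]]] <- TRUE
        dists <- c(dists, D[rg[i], rh[a[i]]])
      }
    }

    ids_t <- 0L
    for (gid in names(new_corr)) {
      prev <- last_match[[gid]]
      if (!is.null(prev) && prev != new_corr[[gid]]) ids_t <- ids_t + 1L
      last_match[[gid]] <- new_corr[[gid]]
    }
    c_t <- sum(used_g)
    fn_t <- nrow(g) - c_t
    fp_t <- nrow(h) - sum(used_h)
    per_frame[[fi]] <- data.frame(frame = t, gt = nrow(g), matches = c_t,
                                  fn = fn_t, fp = fp_t, ids = ids_t,
                                  mean_dist = if (c_t) mean(dists) else NA_real_)
    tot$fn <- tot$fn + fn_t; tot$fp <- tot$fp + fp_t
    tot$ids <- tot$ids + ids_t; tot$gt <- tot$gt + nrow(g)
    tot$c <- tot$c + c_t; tot$dist <- tot$dist + sum(dists)
    corr <- new_corr
  }

  motp_px <- if (tot$c > 0) tot$dist / tot$c else NA_real_
  if (gate_type == "iou") motp_px <- motp_px  # already a 1-IOU distance
  list(mota = 1 - (tot$fn + tot$fp + tot$ids) / max(tot$gt, 1L),
       motp_px = motp_px,
       motp_norm = if (gate_type == "center") motp_px / gate else motp_px,
       ids = tot$ids,
       counts = tot,
       frames = do.call(rbind, per_frame))
}

#' Ablation harness over tracker variants
#'
#' Runs the same detection stream through the four tracker variants --
#' stock (fixed gate, no cascade), dynamic gate only, cascade only, and
#' both -- and scores each against ground truth with [clear_mot()].
#'
#' @param detections per-frame detection stream (bounding-box data frame).
#' @param gt ground-truth records.
#' @param n_frames frames in the stream.
#' @param cfg a [tracker_config()].
#' @param gate,gate_type passed to [clear_mot()].
#' @return data frame with one row per variant: `variant, ids, mota,
#'   motp_px, motp_norm`.
#' @export
compare_tracker_variants <- function(detections, gt, n_frames,
                                     cfg = tracker_config(), gate = 50,
                                     gate_type = "center") {
  variants <- list(
    sort        = c(dynamic_iou = FALSE, cascade = FALSE),
    sort_iou    = c(dynamic_iou = TRUE, cascade = FALSE),
    sort_cascade = c(dynamic_iou = FALSE, cascade = TRUE),
    sort_pest   = c(dynamic_iou = TRUE, cascade = TRUE))
  rows <- lapply(names(variants), function(nm) {
    v <- variants[[nm]]
    tr <- track_sequence(detections, n_frames, cfg,
                         dynamic_iou = v[["dynamic_iou"]],
                         cascade = v[["cascade"]])
    rec <- tracks_to_records(tr)
    m <- clear_mot(gt, rec, gate = gate, gate_type = gate_type)
    data.frame(variant = nm, ids = m$ids, mota = m$mota,
               motp_px = m$motp_px, motp_norm = m$motp_norm,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
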