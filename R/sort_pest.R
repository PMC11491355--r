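# Population-aware tracking-by-detection for a fixed number of targets in
# an enclosed observation volume. Extends the classic constant-velocity
# Kalman + Hungarian-IOU tracker with two strategies:
#   * dynamic IOU gating -- the minimum-IOU acceptance threshold for a
#     track/detection match shrinks linearly with the track's estimated
#     speed, tolerating the larger displacements of fast, erratic flyers;
#   * a cascaded population correction -- the tracker count is capped at
#     the known number of animals: surplus detections are treated as false
#     alarms, shortfalls trigger a second, Euclidean-distance matching
#     pass, and unmatched trackers coast for a retention window instead of
#     being deleted.

#' Tracker configuration
#'
#' @param n_expected known number of targets in the enclosure.
#' @param max_age frames an unmatched tracker is retained while coasting.
#' @param second_match_dist center-distance acceptance threshold (px) for
#'   the second, Euclidean matching pass.
#' @param iou_slope,iou_intercept coefficients of the speed-dependent IOU
#'   gate `threshold = iou_slope * v + iou_intercept` with `v` the track
#'   speed in px/frame.
#' @param iou_floor,iou_ceiling clamp bounds for the gate; the linear form
#'   goes non-positive at high speed and an unclamped gate would accept
#'   arbitrary non-overlap.
#' @param max_age_plain retention used when the cascade is disabled (the
#'   stock tracker deletes unmatched tracks after one frame).
#' @return list of class `tracker_config`.
#' @export
tracker_config <- function(n_expected = 5, max_age = 20,
                           second_match_dist = 20, iou_slope = -0.025,
                           iou_intercept = 0.3, iou_floor = 0.05,
                           iou_ceiling = 0.3, max_age_plain = 1) {
  stopifnot(n_expected >= 1, max_age >= 1, second_match_dist > 0,
            iou_floor > 0, iou_floor < iou_ceiling, iou_ceiling <= 1)
  structure(list(n_expected = as.integer(n_expected), max_age = max_age,
                 second_match_dist = second_match_dist,
                 iou_slope = iou_slope, iou_intercept = iou_intercept,
                 iou_floor = iou_floor, iou_ceiling = iou_ceiling,
                 max_age_plain = max_age_plain),
            class = "tracker_config")
}

#' Speed-dependent IOU acceptance threshold
#'
#' Linear in the track speed, clamped to `[iou_floor, iou_ceiling]`:
#' fast tracks are matched under a looser overlap requirement, slow tracks
#' under a stricter one.
#'
#' @param v track speed in px/frame (non-negative).
#' @param cfg a [tracker_config()].
#' @return threshold in `[iou_floor, iou_ceiling]`.
#' @export
dynamic_iou_threshold <- function(v, cfg = tracker_config()) {
  if (any(v < 0)) stop("speed v must be non-negative")
  pmin(pmax(cfg$iou_slope * v + cfg$iou_intercept, cfg$iou_floor),
       cfg$iou_ceiling)
}

new_track <- function(id, box) {
  list(id = id, kf = kf_init(box), time_since_update = 0L,
       history = cbind(frame = box$frame, x = box$x, y = box$y,
                       w = box$w, h = box$h),
       status = "active", predicted = box)
}

#' Predicted box of a track
#'
#' Constant-velocity prediction of the track's center and area; the aspect
#' ratio is held. Call advances the filter one frame.
#'
#' @param track a track object from [track_sequence()] internals.
#' @return list with the advanced `track` and its predicted `box`.
#' @export
predict_track <- function(track) {
  track$kf <- kf_predict(track$kf)
  track$predicted <- z_to_box(track$kf$x[1:4])
  list(track = track, box = track$predicted)
}

#' Associate detections to tracks
#'
#' Optimal assignment on cost `1 - IOU` between the tracks' predicted boxes
#' and the detections, followed by gating: a pair whose IOU falls below the
#' track's acceptance threshold (speed-dependent when `dynamic = TRUE`,
#' fixed at `iou_intercept` otherwise) is voided and both sides are
#' reported unmatched.
#'
#' @param tracks list of track objects (with current predictions).
#' @param detections bounding-box data frame for one frame.
#' @param cfg a [tracker_config()].
#' @param dynamic use the speed-dependent gate?
#' @return list with `matches` (two-column matrix `track`, `det`),
#'   `unmatched_tracks`, `unmatched_detections` (index vectors).
#' @export
associate <- function(tracks, detections, cfg = tracker_config(),
                      dynamic = TRUE) {
  nt <- length(tracks); nd <- nrow(detections)
  if (nt == 0 || nd == 0) {
    return(list(matches = cbind(track = integer(), det = integer()),
                unmatched_tracks = seq_len(nt),
                unmatched_detections = seq_len(nd)))
  }
  pred <- do.call(rbind, lapply(tracks, `[[`, "predicted"))
  M <- iou_matrix(pred, detections)
  a <- solve_assignment(1 - M)
  matches <- NULL
  for (i in seq_len(nt)) {
    if (is.na(a[i])) next
    thr <- if (dynamic) dynamic_iou_threshold(kf_speed(tracks[[i]]$kf), cfg)
           else cfg$iou_intercept
    if (M[i, a[i]] >= thr) matches <- rbind(matches, c(i, a[i]))
  }
  if (is.null(matches)) matches <- cbind(track = integer(), det = integer())
  colnames(matches) <- c("track", "det")
  list(matches = matches,
       unmatched_tracks = setdiff(seq_len(nt), matches[, "track"]),
       unmatched_detections = setdiff(seq_len(nd), matches[, "det"]))
}

apply_match <- function(track, det, frame) {
  track$kf <- kf_update(track$kf, det)
  track$time_since_update <- 0L
  b <- z_to_box(track$kf$x[1:4])
  track$history <- rbind(track$history,
                         cbind(frame = frame, x = b$x, y = b$y,
                               w = b$w, h = b$h))
  track$status <- "active"
  track
}

#' Population-aware post-association update
#'
#' Applies the cascaded correction after [associate()], comparing the
#' detection count to the known population size:
#' more detections than targets means false alarms are present, so no new
#' trackers are started; at or below the expected count, leftover
#' detections and trackers go through a second optimal matching on center
#' Euclidean distance (accepting pairs within `second_match_dist`), so a
#' tracker that failed the overlap gate re-locks onto a nearby detection
#' instead of coasting beside it; fewer detections than targets means
#' misses, so unmatched trackers coast and are deleted only after
#' `max_age` frames without support. New tracks are seeded from unmatched
#' detections only while the population is below `n_expected`. Matched
#' tracks are Kalman-corrected; coasting tracks record no output box.
#'
#' @param tracks list of track objects.
#' @param assoc result of [associate()].
#' @param detections this frame's detections.
#' @param cfg a [tracker_config()].
#' @param frame 0-based frame index.
#' @param next_id next unused track id.
#' @param cascade apply the population logic? `FALSE` gives the stock
#'   behaviour: every unmatched detection starts a track and retention is
#'   `max_age_plain`.
#' @return list with updated `tracks` and `next_id`.
#' @export
cascade_update <- function(tracks, assoc, detections, cfg = tracker_config(),
                           frame = 0L, next_id = 1L, cascade = TRUE) {
  if (cascade && is.null(cfg$n_expected)) stop("n_expected must be configured")
  mt <- assoc$matches
  for (k in seq_len(nrow(mt)))
    tracks[[mt[k, "track"]]] <-
      apply_match(tracks[[mt[k, "track"]]], detections[mt[k, "det"], , drop = FALSE],
                  frame)
  un_t <- assoc$unmatched_tracks
  un_d <- assoc$unmatched_detections

  if (cascade) {
    nd <- nrow(detections)
    if (nd <= cfg$n_expected && length(un_t) && length(un_d)) {
      # second matching on center Euclidean distance
      ct <- do.call(rbind, lapply(tracks[un_t], function(tr)
        box_centers(tr$predicted)))
      cd <- box_centers(detections[un_d, , drop = FALSE])
      D <- sqrt(outer(ct[, 1], cd[, 1], "-")^2 + outer(ct[, 2], cd[, 2], "-")^2)
      a <- solve_assignment(D)
      matched2 <- integer()
      for (i in seq_along(un_t)) {
        if (is.na(a[i]) || D[i, a[i]] > cfg$second_match_dist) next
        tracks[[un_t[i]]] <- apply_match(tracks[[un_t[i]]],
                                         detections[un_d[a[i]], , drop = FALSE],
                                         frame)
        matched2 <- c(matched2, i)
      }
      un_d <- un_d[!seq_along(un_d) %in% a[matched2]]
      un_t <- un_t[!seq_along(un_t) %in% matched2]
    }
    # seed new tracks only while the population is short
    for (j in un_d) {
      if (length(tracks) >= cfg$n_expected) break
      tracks[[length(tracks) + 1]] <-
        new_track(next_id, detections[j, , drop = FALSE])
      next_id <- next_id + 1L
    }
    age_limit <- cfg$max_age
  } else {
    for (j in un_d) {
      tracks[[length(tracks) + 1]] <-
        new_track(next_id, detections[j, , drop = FALSE])
      next_id <- next_id + 1L
    }
    age_limit <- cfg$max_age_plain
  }

  for (i in un_t) {
    tracks[[i]]$time_since_update <- tracks[[i]]$time_since_update + 1L
    tracks[[i]]$status <- "coasting"
  }
  keep <- vapply(tracks, function(tr) tr$time_since_update <= age_limit,
                 logical(1))
  list(tracks = tracks[keep], next_id = next_id)
}

#' Track a detection stream
#'
#' Runs the full per-frame loop -- predict, associate, population-aware
#' update -- over an ordered detection stream. Deterministic given inputs.
#'
#' @param detections bounding-box data frame covering frames `0..n_frames-1`.
#' @param n_frames number of frames.
#' @param cfg a [tracker_config()].
#' @param dynamic_iou use the speed-dependent IOU gate?
#' @param cascade use the population-aware cascade?
#' @return list of track objects; each has `id` and a `history` matrix of
#'   per-frame corrected boxes (coast frames absent).
#' @export
track_sequence <- function(detections, n_frames, cfg = tracker_config(),
                           dynamic_iou = TRUE, cascade = TRUE) {
  tracks <- list()
  finished <- list()
  next_id <- 1L
  for (t in seq_len(n_frames) - 1L) {
    det <- detections[detections$frame == t, , drop = FALSE]
    for (i in seq_along(tracks)) {
      p <- predict_track(tracks[[i]])
      tracks[[i]] <- p$track
    }
    assoc <- associate(tracks, det, cfg, dynamic = dynamic_iou)
    before_ids <- vapply(tracks, function(tr) as.integer(tr$id), integer(1))
    res <- cascade_update(tracks, assoc, det, cfg, frame = t,
                          next_id = next_id, cascade = cascade)
    after_ids <- vapply(res$tracks, function(tr) as.integer(tr$id), integer(1))
    dropped <- setdiff(before_ids, after_ids)
    if (length(dropped)) {
      finished <- c(finished,
                    tracks[match(dropped, before_ids)])
    }
    tracks <- res$tracks
    next_id <- res$next_id
  }
  c(finished, tracks)
}

#' Convert tracks to MOT-style records
#'
#' @param tracks result of [track_sequence()].
#' @return bounding-box data frame with the track ids in `id`.
#' @export
tracks_to_records <- function(tracks) {
  if (length(tracks) == 0) return(empty_boxes())
  out <- do.call(rbind, lapply(tracks, function(tr) {
    h <- as.data.frame(tr$history)
    h$id <- tr$id
    h
  }))
  res <- bounding_boxes(frame = out$frame, x = out$x, y = out$y, w = out$w,
                        h = out$h, conf = 1, source = "fused", id = out$id)
  res[order(res$frame, res$id), , drop = FALSE]
}
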