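# Binocular 3D reconstruction for a rectified parallel rig. Depth follows
# from the horizontal disparity d between corresponding image points,
# Zc = f * B / d, and the full camera-frame position from back-projection
# through the intrinsics, Pc = inv(K) [u, v, 1]' Zc. Coordinates are meters
# in the left-camera frame (x right, y down, z forward).

#' Depth from disparity
#'
#' @param f focal length in pixels.
#' @param B baseline in meters.
#' @param d disparity in pixels (left column minus right column); must be
#'   positive for a point in front of the rig.
#' @return depth `Zc` in meters.
#' @export
disparity_to_depth <- function(f, B, d) {
  stopifnot(f > 0, B > 0)
  if (any(d <= 0)) stop("disparity must be positive (point at or behind infinity)")
  f * B / d
}

#' Back-project a pixel to camera coordinates
#'
#' @param u,v pixel coordinates.
#' @param Zc depth in meters (positive).
#' @param K 3x3 intrinsic matrix.
#' @return matrix with columns `Xc, Yc, Zc` (meters).
#' @export
backproject <- function(u, v, Zc, K) {
  stopifnot(length(u) == length(v), length(Zc) %in% c(1, length(u)))
  if (any(Zc <= 0)) stop("Zc must be positive")
  Kinv <- tryCatch(solve(K), error = function(e) stop("singular intrinsic matrix K"))
  p <- Kinv %*% rbind(u, v, 1)
  out <- t(p) * Zc
  colnames(out) <- c("Xc", "Yc", "Zc")
  out
}

#' Pinhole projection into a camera of the rig
#'
#' Forward model used by the synthetic generator and the round-trip tests:
#' projects left-camera-frame points into the left (`cam = "left"`) or
#' right (`cam = "right"`, shifted by the baseline) camera.
#'
#' @param pts matrix/data frame with columns `Xc, Yc, Zc` (meters).
#' @param rig a [camera_rig()].
#' @param cam `"left"` or `"right"`.
#' @return matrix with columns `u, v` in pixels.
#' @export
project_points <- function(pts, rig, cam = c("left", "right")) {
  cam <- match.arg(cam)
  pts <- as.matrix(pts)
  X <- pts[, 1] - if (cam == "right") rig$B else 0
  uvw <- rig$K %*% rbind(X, pts[, 2], pts[, 3])
  out <- cbind(u = uvw[1, ] / uvw[3, ], v = uvw[2, ] / uvw[3, ])
  out
}

#' Pair tracks across the two cameras
#'
#' On a rectified parallel rig, corresponding points share an image row.
#' Tracks are paired by optimal assignment on a cost combining the median
#' absolute row difference of temporally overlapping boxes and the
#' temporal-overlap deficit; pairs whose median row difference exceeds
#' `row_epsilon`, or with no common frames, are rejected.
#'
#' @param left,right track-record data frames ([tracks_to_records()]).
#' @param row_epsilon maximum acceptable median row difference in pixels.
#' @return data frame with columns `left_id`, `right_id`.
#' @export
match_stereo_tracks <- function(left, right, row_epsilon = 10) {
  lids <- sort(unique(left$id)); rids <- sort(unique(right$id))
  if (length(lids) == 0 || length(rids) == 0)
    return(data.frame(left_id = integer(), right_id = integer()))
  cost <- matrix(Inf, length(lids), length(rids))
  for (i in seq_along(lids)) {
    li <- left[left$id == lids[i], , drop = FALSE]
    vl <- setNames(li$y + li$h / 2, li$frame)
    for (j in seq_along(rids)) {
      rj <- right[right$id == rids[j], , drop = FALSE]
      common <- intersect(li$frame, rj$frame)
      if (length(common) == 0) next
      vr <- setNames(rj$y + rj$h / 2, rj$frame)
      dv <- stats::median(abs(vl[as.character(common)] - vr[as.character(common)]))
      if (dv > row_epsilon) next
      overlap_deficit <- 1 - length(common) /
        max(length(unique(li$frame)), length(unique(rj$frame)))
      cost[i, j] <- dv + row_epsilon * overlap_deficit
    }
  }
  a <- solve_assignment(cost)
  keep <- which(!is.na(a))
  data.frame(left_id = lids[keep], right_id = rids[a[keep]])
}

#' Reconstruct one 3D trajectory from a stereo track pair
#'
#' For every frame the two tracks share, the disparity of the box centers
#' `d = uL - uR` gives depth via [disparity_to_depth()] and the left center
#' is back-projected through the intrinsics. On a rectified rig
#' corresponding points share an image row, so frames violating that
#' epipolar constraint (row difference above `row_epsilon`, e.g. where one
#' camera sees two targets as a single merged blob) are dropped, as are
#' frames with non-positive disparity; both with a warning.
#'
#' @param left,right track-record data frames for one track each.
#' @param rig a [camera_rig()].
#' @param track_id id stored in the output.
#' @param row_epsilon per-frame row-consistency gate in pixels.
#' @return data frame `track_id, frame, Xc, Yc, Zc` (meters, left-camera
#'   frame), frames strictly increasing.
#' @export
reconstruct_trajectory <- function(left, right, rig, track_id = 1L,
                                   row_epsilon = 10) {
  common <- sort(intersect(left$frame, right$frame))
  if (length(common) == 0) stop("tracks share no frames")
  li <- left[match(common, left$frame), , drop = FALSE]
  ri <- right[match(common, right$frame), , drop = FALSE]
  uL <- li$x + li$w / 2; vL <- li$y + li$h / 2
  uR <- ri$x + ri$w / 2; vR <- ri$y + ri$h / 2
  d <- uL - uR
  ok <- d > 0
  if (any(!ok))
    warning(sum(!ok), " frame(s) with non-positive disparity dropped")
  row_ok <- abs(vL - vR) <= row_epsilon
  if (any(ok & !row_ok))
    warning(sum(ok & !row_ok),
            " frame(s) violating the epipolar row constraint dropped")
  ok <- ok & row_ok
  if (!any(ok))
    return(data.frame(track_id = integer(), frame = integer(),
                      Xc = numeric(), Yc = numeric(), Zc = numeric()))
  Zc <- disparity_to_depth(rig$f, rig$B, d[ok])
  P <- backproject(uL[ok], vL[ok], Zc, rig$K)
  data.frame(track_id = track_id, frame = common[ok],
             Xc = P[, 1], Yc = P[, 2], Zc = P[, 3])
}

#' Reconstruct all paired tracks
#'
#' @param left,right track-record data frames (many tracks).
#' @param rig a [camera_rig()].
#' @param pairs optional pairing from [match_stereo_tracks()]; computed
#'   when omitted.
#' @return data frame of 3D trajectories, `track_id` = left track id.
#' @export
reconstruct_all <- function(left, right, rig, pairs = NULL) {
  if (is.null(pairs)) pairs <- match_stereo_tracks(left, right)
  out <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    out[[k]] <- reconstruct_trajectory(
      left[left$id == pairs$left_id[k], , drop = FALSE],
      right[right$id == pairs$right_id[k], , drop = FALSE],
      rig, track_id = pairs$left_id[k])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) data.frame(track_id = integer(), frame = integer(),
                               Xc = numeric(), Yc = numeric(), Zc = numeric())
  else res
}

#' Point-wise trajectory error
#'
#' Euclidean distances between corresponding points of a reference and a
#' measured point sequence, with summary statistics. Distances are in the
#' units of the inputs; the summary standard deviation is the sample
#' (n - 1) convention.
#'
#' @param theoretical,actual matrices or data frames of aligned 3D points
#'   (equal length, columns x, y, z).
#' @return list with `distances`, `min`, `max`, `mean`, `sd`.
#' @export
trajectory_error <- function(theoretical, actual) {
  a <- as.matrix(theoretical); b <- as.matrix(actual)
  if (nrow(a) != nrow(b)) stop("point sequences differ in length")
  d <- sqrt(rowSums((a - b)^2))
  list(distances = d, min = min(d), max = max(d), mean = mean(d),
       sd = stats::sd(d))
}

#' Bundled LED-marker validation measurements
#'
#' Ten LED markers similar in size to the study animals were hung at known
#' positions in the observation box; their 3D coordinates were measured by
#' tape and, independently, estimated by the binocular pipeline, both
#' expressed in the camera-centered frame in centimeters. These paired
#' coordinates support validation of the 3D positioning error summary.
#'
#' @return data frame with columns `point`, `tx, ty, tz` (pipeline
#'   estimate, cm), `ax, ay, az` (tape-measured reference, cm).
#' @export
led_validation_points <- function() {
  path <- system.file("extdata", "led_validation_points.csv",
                      package = "pesttrack3d")
  read.csv(path, stringsAsFactors = FALSE)
}
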