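# Motion-target enhancement chain for thermal video: adaptive
# Gaussian-mixture background modelling -> median filtering -> morphological
# opening -> component size filtering -> red-channel overlay.

#' Motion segmentation configuration
#'
#' Parameters of the motion-detection chain. The size band
#' `[area_min, area_max]` (pixels squared, inclusive at both ends) is the
#' operating range of target silhouette areas; components outside it are
#' treated as background clutter or merged/oversized blobs.
#'
#' @param gmm_history effective background adaptation horizon in frames; the
#'   per-frame learning rate is `1/min(t, gmm_history)`.
#' @param gmm_components Gaussians per pixel.
#' @param gmm_var_threshold squared-Mahalanobis match gate (16 = 4 sigma).
#' @param median_kernel odd median-filter width in pixels.
#' @param opening_kernel width of the structuring element for opening.
#' @param area_min,area_max inclusive component pixel-count band.
#' @param connectivity 4 or 8 (component neighbourhood).
#' @return list of class `motion_seg_config`.
#' @export
motion_seg_config <- function(gmm_history = 120, gmm_components = 5,
                              gmm_var_threshold = 16, median_kernel = 3,
                              opening_kernel = 3, area_min = 150,
                              area_max = 550, connectivity = 8) {
  stopifnot(area_min < area_max, median_kernel %% 2 == 1, median_kernel >= 3,
            gmm_history >= 1, gmm_components >= 1, gmm_var_threshold > 0,
            connectivity %in% c(4, 8))
  structure(list(gmm_history = gmm_history, gmm_components = gmm_components,
                 gmm_var_threshold = gmm_var_threshold,
                 median_kernel = median_kernel,
                 opening_kernel = opening_kernel,
                 area_min = area_min, area_max = area_max,
                 connectivity = connectivity),
            class = "motion_seg_config")
}

#' Foreground masks from Gaussian-mixture background modelling
#'
#' Runs an online per-pixel mixture-of-Gaussians background model over the
#' frame sequence, in frame order. Pixels poorly explained by the dominant
#' (background) components of their mixture are flagged as foreground.
#' The first frame seeds the model and gets an all-zero mask.
#'
#' @param frames list of grayscale matrices (rows = image y, cols = image x),
#'   constant shape, any intensity scale.
#' @param cfg a [motion_seg_config()].
#' @return list of binary integer masks, one per frame.
#' @export
gmm_foreground <- function(frames, cfg = motion_seg_config()) {
  stopifnot(length(frames) >= 1)
  d <- dim(frames[[1]])
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), d))
      stop("frame ", i, " has a different shape than frame 1")
    storage.mode(frames[[i]]) <- "double"
  }
  .mog_masks(frames, as.integer(cfg$gmm_components), cfg$gmm_var_threshold,
             cfg$gmm_history, 0.9, init_var = 225, min_var = 4,
             max_var = 2500)
}

#' Denoise a foreground mask
#'
#' Median filter then morphological opening, in that order: the median
#' (majority) filter kills isolated speckle, the opening removes thin
#' bridges and regularises blob outlines while preserving compact
#' components. Both steps are binary-mask specialisations (out-of-image
#' neighbours count as background); the structuring element is the full
#' `opening_kernel` x `opening_kernel` square.
#'
#' @param mask binary matrix (0/1).
#' @param cfg a [motion_seg_config()].
#' @return cleaned binary integer matrix of the same shape.
#' @export
clean_mask <- function(mask, cfg = motion_seg_config()) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  m <- .binary_median(m, as.integer(cfg$median_kernel))
  .binary_opening(m, as.integer(cfg$opening_kernel))
}

#' Extract motion boxes from a cleaned mask
#'
#' Labels connected components and keeps those whose pixel count lies inside
#' the configured size band (inclusive at both bounds). Each kept component
#' yields one bounding box with confidence 1 and source `"motion"`.
#'
#' @param mask cleaned binary matrix.
#' @param cfg a [motion_seg_config()].
#' @param frame 0-based frame index stored in the output.
#' @return bounding-box data frame (possibly empty).
#' @export
extract_motion_boxes <- function(mask, cfg = motion_seg_config(), frame = 0L) {
  storage.mode(mask) <- "integer"
  lab <- .label_components(mask, as.integer(cfg$connectivity))
  st <- lab$stats
  keep <- st$count >= cfg$area_min & st$count <= cfg$area_max
  st <- st[keep, , drop = FALSE]
  if (nrow(st) == 0) return(empty_boxes())
  bounding_boxes(frame = rep(frame, nrow(st)), x = st$xmin, y = st$ymin,
                 w = st$xmax - st$xmin + 1, h = st$ymax - st$ymin + 1,
                 conf = 1, source = "motion")
}

#' Red-channel enhancement of detected motion targets
#'
#' Replicates the grayscale frame into three channels and saturates the red
#' channel inside the union of the given boxes, raising the visual contrast
#' of moving targets. Overlapping boxes enhance their union once.
#'
#' @param frame grayscale matrix.
#' @param boxes bounding-box data frame (pixel coordinates, 0-based).
#' @param red_value intensity written to the red channel inside boxes.
#' @return array `c(nrow, ncol, 3)` with channels R, G, B.
#' @export
enhance_frame <- function(frame, boxes, red_value = max(255, max(frame))) {
  out <- array(frame, c(nrow(frame), ncol(frame), 3))
  if (nrow(boxes) > 0) {
    sel <- matrix(FALSE, nrow(frame), ncol(frame))
    for (i in seq_len(nrow(boxes))) {
      x1 <- floor(boxes$x[i]) + 1; y1 <- floor(boxes$y[i]) + 1
      x2 <- ceiling(boxes$x[i] + boxes$w[i]); y2 <- ceiling(boxes$y[i] + boxes$h[i])
      if (x1 < 1 || y1 < 1 || x2 > ncol(frame) || y2 > nrow(frame))
        warning("box ", i, " exceeds frame bounds; clipping")
      x1 <- max(x1, 1); y1 <- max(y1, 1)
      x2 <- min(x2, ncol(frame)); y2 <- min(y2, nrow(frame))
      if (x2 >= x1 && y2 >= y1) sel[y1:y2, x1:x2] <- TRUE
    }
    red <- out[, , 1]
    red[sel] <- red_value
    out[, , 1] <- red
  }
  out
}

#' Run the full motion-detection chain over a sequence
#'
#' Background modelling, mask clean-up and size-filtered box extraction per
#' frame. Optional warm-up frames (e.g. target-free background renders) can
#' be prepended to settle the background model; their masks are discarded
#' and frame indices refer to the main sequence only.
#'
#' @param frames list of grayscale matrices.
#' @param cfg a [motion_seg_config()].
#' @param warmup_frames optional list of grayscale matrices fed to the
#'   background model before the sequence proper.
#' @return list with `boxes` (bounding-box data frame over all frames) and
#'   `masks` (cleaned masks).
#' @export
detect_motion <- function(frames, cfg = motion_seg_config(),
                          warmup_frames = list()) {
  n_warm <- length(warmup_frames)
  masks <- gmm_foreground(c(warmup_frames, frames), cfg)
  masks <- masks[seq_along(frames) + n_warm]
  boxes <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    masks[[i]] <- clean_mask(masks[[i]], cfg)
    boxes[[i]] <- extract_motion_boxes(masks[[i]], cfg, frame = i - 1L)
  }
  list(boxes = do.call(rbind, boxes), masks = masks)
}
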