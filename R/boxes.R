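#' Construct a bounding-box table
#'
#' Detections and annotations are kept in a plain data frame with one row per
#' box. Coordinates follow the image convention: origin at the top-left
#' pixel, x rightward, y downward, 0-based, with real-valued (sub-pixel)
#' positions permitted. `(x, y)` is the top-left corner of the box.
#'
#' @param frame 0-based frame index (non-negative integer vector).
#' @param x,y top-left corner in pixels.
#' @param w,h box width and height in pixels; must be positive.
#' @param conf detection confidence in `[0, 1]`.
#' @param source one of `"appearance"`, `"motion"`, `"fused"`.
#' @param id optional track/annotation identity (`-1` for plain detections).
#' @return data frame with columns `frame, id, x, y, w, h, conf, source`.
#' @export
bounding_boxes <- function(frame, x, y, w, h, conf = 1,
                           source = "appearance", id = -1L) {
  df <- data.frame(frame = as.integer(frame), id = as.integer(id),
                   x = as.numeric(x), y = as.numeric(y),
                   w = as.numeric(w), h = as.numeric(h),
                   conf = as.numeric(conf), source = as.character(source),
                   stringsAsFactors = FALSE)
  validate_boxes(df)
  df
}

#' @rdname bounding_boxes
#' @param boxes a bounding-box data frame.
#' @export
validate_boxes <- function(boxes) {
  stopifnot(is.data.frame(boxes))
  need <- c("frame", "x", "y", "w", "h", "conf")
  miss <- setdiff(need, names(boxes))
  if (length(miss))
    stop("bounding-box table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(boxes) == 0) return(invisible(boxes))
  if (any(boxes$frame < 0)) stop("frame indices must be non-negative")
  if (any(boxes$w <= 0) || any(boxes$h <= 0))
    stop("box widths and heights must be positive")
  if (any(boxes$conf < 0 | boxes$conf > 1))
    stop("confidences must lie in [0, 1]")
  invisible(boxes)
}

#' An empty bounding-box table
#'
#' @return zero-row data frame with the bounding-box columns.
#' @export
empty_boxes <- function() {
  data.frame(frame = integer(), id = integer(), x = numeric(), y = numeric(),
             w = numeric(), h = numeric(), conf = numeric(),
             source = character(), stringsAsFactors = FALSE)
}

#' Box centers
#'
#' @param boxes bounding-box data frame.
#' @return two-column matrix of center coordinates `(cx, cy)`.
#' @export
box_centers <- function(boxes) {
  cbind(cx = boxes$x + boxes$w / 2, cy = boxes$y + boxes$h / 2)
}

#' Intersection over union of two boxes
#'
#' The standard box-similarity measure: the area of the intersection
#' rectangle divided by the area of the union. Vectorised over rows; both
#' arguments are recycled to a common length.
#'
#' @param a,b bounding-box data frames (columns `x, y, w, h`).
#' @return numeric vector of IOU values in `[0, 1]`.
#' @export
iou <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  if (n == 0) return(numeric())
  ia <- rep_len(seq_len(max(nrow(a), 1L)), n)
  ib <- rep_len(seq_len(max(nrow(b), 1L)), n)
  ax1 <- a$x[ia]; ay1 <- a$y[ia]; ax2 <- ax1 + a$w[ia]; ay2 <- ay1 + a$h[ia]
  bx1 <- b$x[ib]; by1 <- b$y[ib]; bx2 <- bx1 + b$w[ib]; by2 <- by1 + b$h[ib]
  iw <- pmax(0, pmin(ax2, bx2) - pmax(ax1, bx1))
  ih <- pmax(0, pmin(ay2, by2) - pmax(ay1, by1))
  inter <- iw * ih
  union <- a$w[ia] * a$h[ia] + b$w[ib] * b$h[ib] - inter
  inter / union
}

#' Pairwise IOU matrix
#'
#' @param a,b bounding-box data frames.
#' @return `nrow(a)` by `nrow(b)` matrix of IOU values.
#' @export
iou_matrix <- function(a, b) {
  m <- matrix(0, nrow(a), nrow(b))
  if (nrow(a) == 0 || nrow(b) == 0) return(m)
  for (j in seq_len(nrow(b))) m[, j] <- iou(a, b[j, , drop = FALSE])
  m
}
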