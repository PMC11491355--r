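# File interfaces: MOT16/MOTChallenge CSV tracking files, detection lists,
# flat key/value stereo calibration configs, and 3D trajectory exports.
# Frames are 1-based in files and 0-based in memory; the conversion happens
# here and nowhere else.

fmt_num <- function(v) {
  s <- sprintf("%.4f", v)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

#' Read a MOT16/MOTChallenge tracking file
#'
#' MOT16 files are comma-separated with one row per box:
#' `frame,id,x,y,w,h,conf,a,b,c` where the last three fields are
#' placeholders (`-1` in 2D tracking files). Frames are converted from the
#' 1-based file convention to 0-based indices; records are returned ordered
#' by frame, then id.
#'
#' @param path file to read.
#' @param source tag stored in the `source` column of the result.
#' @return bounding-box data frame with extra columns `id` and the three
#'   placeholder fields `p1, p2, p3`.
#' @export
read_mot16 <- function(path, source = "appearance") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    out <- empty_boxes()
    out$p1 <- numeric(); out$p2 <- numeric(); out$p3 <- numeric()
    return(out)
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 7)
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s: expected >= 7 fields, got %d",
                 bad[1], path, nf[bad[1]]))
  num <- suppressWarnings(lapply(parts, function(p) as.numeric(p[1:7])))
  nas <- which(vapply(num, function(v) anyNA(v), logical(1)))
  if (length(nas))
    stop(sprintf("malformed row at line %d of %s: non-numeric field", nas[1], path))
  m <- do.call(rbind, num)
  trail <- t(vapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[8:10]))
    v[is.na(v)] <- -1
    v
  }, numeric(3)))
  df <- data.frame(frame = as.integer(m[, 1]) - 1L, id = as.integer(m[, 2]),
                   x = m[, 3], y = m[, 4], w = m[, 5], h = m[, 6],
                   conf = m[, 7], source = source,
                   p1 = trail[, 1], p2 = trail[, 2], p3 = trail[, 3],
                   stringsAsFactors = FALSE)
  if (any(df$frame < 0)) stop("MOT16 frames must be >= 1 in ", path)
  if (any(df$w <= 0 | df$h <= 0))
    stop("negative or zero box width/height in ", path)
  df$conf <- pmin(pmax(df$conf, 0), 1)
  df[order(df$frame, df$id), , drop = FALSE]
}

#' Write a MOT16/MOTChallenge tracking file
#'
#' Inverse of [read_mot16()]: frames are re-offset to the 1-based file
#' convention on write. Reading a conforming file and writing it back
#' reproduces it byte for byte.
#'
#' @param records bounding-box data frame (columns `frame, id, x, y, w, h,
#'   conf`; optional placeholders `p1, p2, p3`, default `-1`).
#' @param path output file.
#' @export
write_mot16 <- function(records, path) {
  validate_boxes(records)
  p1 <- if ("p1" %in% names(records)) records$p1 else rep(-1, nrow(records))
  p2 <- if ("p2" %in% names(records)) records$p2 else rep(-1, nrow(records))
  p3 <- if ("p3" %in% names(records)) records$p3 else rep(-1, nrow(records))
  lines <- if (nrow(records) == 0) character() else
    paste(records$frame + 1L, records$id, fmt_num(records$x),
          fmt_num(records$y), fmt_num(records$w), fmt_num(records$h),
          fmt_num(records$conf), fmt_num(p1), fmt_num(p2), fmt_num(p3),
          sep = ",")
  con <- file(path, "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read or write a detection list
#'
#' Detection files use the MOT16 column layout with `id = -1`, as in
#' MOTChallenge detection files, so externally produced appearance
#' detections from any trained detector can be plugged in.
#'
#' @param path detection CSV.
#' @param source tag for the `source` column.
#' @return bounding-box data frame.
#' @export
read_detections <- function(path, source = "appearance") {
  read_mot16(path, source = source)
}

#' @rdname read_detections
#' @param boxes bounding-box data frame; the id column is forced to `-1`.
#' @export
write_detections <- function(boxes, path) {
  boxes$id <- rep(-1L, nrow(boxes))
  write_mot16(boxes, path)
}

#' Stereo camera rig
#'
#' Geometry of a rectified parallel binocular rig: shared intrinsic matrix
#' `K`, focal length `f` in pixels, baseline `B` in meters, and image size.
#'
#' @param f focal length in pixels.
#' @param B baseline in meters.
#' @param width,height image size in pixels.
#' @param cx,cy principal point (defaults to the image center).
#' @param K optional explicit 3x3 intrinsic matrix; built from `f, cx, cy`
#'   when omitted.
#' @return object of class `camera_rig`.
#' @export
camera_rig <- function(f, B, width = 640L, height = 480L,
                       cx = width / 2, cy = height / 2, K = NULL) {
  if (is.null(K)) K <- matrix(c(f, 0, cx, 0, f, cy, 0, 0, 1), 3, 3, byrow = TRUE)
  K <- matrix(as.numeric(K), 3, 3)
  if (!is.finite(f) || f <= 0) stop("focal length f must be positive")
  if (!is.finite(B) || B <= 0) stop("baseline B must be positive")
  if (K[1, 1] <= 0 || K[2, 2] <= 0) stop("K must have positive focal terms")
  if (abs(det(K)) < 1e-12) stop("intrinsic matrix K is singular")
  structure(list(K = K, f = f, B = B,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_rig")
}

#' @export
print.camera_rig <- function(x, ...) {
  cat(sprintf("camera_rig: %dx%d px, f = %g px, B = %g m\n",
              x$width, x$height, x$f, x$B))
  invisible(x)
}

#' Read or write a stereo calibration config
#'
#' The calibration file is a flat key/value text config with one entry per
#' line (`key value...`, `#` comments allowed): `width`, `height`, `f`
#' (pixels), `B` (meters), and `K` as nine row-major numbers.
#'
#' @param path config file.
#' @return a [camera_rig()].
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    p <- strsplit(ln, "[[:space:]]+")[[1]]
    kv[[p[1]]] <- suppressWarnings(as.numeric(p[-1]))
  }
  for (key in c("width", "height", "f", "B", "K")) {
    if (is.null(kv[[key]]) || anyNA(kv[[key]]))
      stop("calibration file ", path, " is missing or has a malformed '",
           key, "' entry")
  }
  if (length(kv$K) != 9)
    stop("calibration file ", path, ": K must have 9 row-major entries")
  camera_rig(f = kv$f, B = kv$B, width = kv$width, height = kv$height,
             K = matrix(kv$K, 3, 3, byrow = TRUE))
}

#' @rdname read_calibration
#' @param rig a [camera_rig()].
#' @export
write_calibration <- function(rig, path) {
  lines <- c("# stereo calibration (flat key/value)",
             paste("width", rig$width), paste("height", rig$height),
             paste("f", fmt_num(rig$f)), paste("B", fmt_num(rig$B)),
             paste("K", paste(fmt_num(t(rig$K)), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a 3D trajectory export
#'
#' Plain CSV with header `track_id,frame,Xc,Yc,Zc`; coordinates are meters
#' in the left-camera frame, frames 0-based.
#'
#' @param traj data frame with those columns (one or more tracks).
#' @param path CSV file.
#' @export
write_trajectory3d <- function(traj, path) {
  stopifnot(all(c("track_id", "frame", "Xc", "Yc", "Zc") %in% names(traj)))
  write.csv(traj[, c("track_id", "frame", "Xc", "Yc", "Zc")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory3d
#' @export
read_trajectory3d <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("track_id", "frame", "Xc", "Yc", "Zc") %in% names(df)))
  df
}
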