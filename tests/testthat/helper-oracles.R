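# Independent brute-force oracles used to validate the fast implementations.

# IOU by integer-pixel set enumeration (integer-valued boxes only): a pixel
# (i, j) belongs to a box when x <= j < x + w and y <= i < y + h.
iou_bruteforce <- function(a, b) {
  pix <- function(bx) {
    g <- expand.grid(x = seq(bx$x, bx$x + bx$w - 1),
                     y = seq(bx$y, bx$y + bx$h - 1))
    paste(g$x, g$y)
  }
  pa <- pix(a); pb <- pix(b)
  length(intersect(pa, pb)) / length(union(pa, pb))
}

# Optimal assignment by full permutation enumeration (square or rectangular).
assignment_bruteforce <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  k <- min(n, m)
  best <- Inf; best_assign <- rep(NA_integer_, n)
  rowsets <- if (n == k) list(seq_len(n)) else utils::combn(n, k, simplify = FALSE)
  colperms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in colperms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  colsets <- if (m == k) list(seq_len(m)) else utils::combn(m, k, simplify = FALSE)
  for (rs in rowsets) for (cs in colsets) for (p in colperms(cs)) {
    tot <- sum(cost[cbind(rs, p)])
    if (is.finite(tot) && tot < best) {
      best <- tot
      best_assign <- rep(NA_integer_, n)
      best_assign[rs] <- p
    }
  }
  list(cost = best, assign = best_assign)
}

# Straight-line truth-table evaluator of the three fusion confirmation
# rules for a single appearance/motion situation. Mirrors the rule text
# only, not the package implementation.
fusion_truth_table <- function(app_conf, motion_count, center_dist, pair_iou,
                               cfg = fusion_config()) {
  has_app <- !is.na(app_conf) && app_conf >= cfg$appearance_conf_floor
  has_mot <- !is.na(motion_count)
  paired <- has_app && has_mot && center_dist <= cfg$center_gate_px
  rule3 <- paired && pair_iou > cfg$iou_confirm
  rule1 <- has_app && app_conf > cfg$appearance_conf_solo
  rule2 <- has_mot && motion_count > cfg$motion_persistence_frames &&
    !rule3   # a pair confirmed by rule 3 emits one box, not two
  list(app_kept = rule3 || rule1, motion_kept = rule2)
}

# Exhaustive CLEAR-MOT correspondence search for tiny scenes: enumerates
# every per-frame matching (keeping the previous correspondence when still
# feasible is NOT imposed -- instead all correspondence sequences are
# enumerated and the CLEAR objective order (maximise matches, then apply
# the metric definitions) is followed). Distances gated at `gate`.
clearmot_bruteforce <- function(gt, hyp, gate = 50) {
  frames <- sort(unique(c(gt$frame, hyp$frame)))
  # enumerate matchings per frame: list of matrices (gt idx -> hyp idx)
  all_matchings <- function(ng, nh, ok) {
    res <- list()
    rec <- function(gi, used, cur) {
      if (gi > ng) { res[[length(res) + 1]] <<- cur; return() }
      rec(gi + 1, used, cur)                       # gt gi unmatched
      for (hj in seq_len(nh)) {
        if (!used[hj] && ok[gi, hj]) {
          used2 <- used; used2[hj] <- TRUE
          rec(gi + 1, used2, rbind(cur, c(gi, hj)))
        }
      }
    }
    rec(1, rep(FALSE, max(nh, 1)), matrix(integer(), 0, 2))
    res
  }
  per_frame <- lapply(frames, function(t) {
    g <- gt[gt$frame == t, , drop = FALSE]
    h <- hyp[hyp$frame == t, , drop = FALSE]
    cg <- box_centers(g); chp <- box_centers(h)
    D <- if (nrow(g) && nrow(h))
      sqrt(outer(cg[, 1], chp[, 1], "-")^2 + outer(cg[, 2], chp[, 2], "-")^2)
    else matrix(numeric(), nrow(g), nrow(h))
    list(g = g, h = h, matchings = all_matchings(nrow(g), nrow(h), D <= gate))
  })
  # CLEAR greedy per frame: among max-cardinality matchings, choose the one
  # that minimises switches relative to the running correspondence, then
  # total distance; evaluate the resulting metric.
  best <- list(obj = Inf)
  eval_seq <- function(fi, last_match, fn, fp, ids, gtc) {
    if (fi > length(frames)) {
      tot_gt <- sum(vapply(per_frame, function(x) nrow(x$g), numeric(1)))
      cand <- list(mota = 1 - (fn + fp + ids) / max(tot_gt, 1), ids = ids,
                   obj = fn + fp + ids)
      if (cand$obj < best$obj) best <<- cand
      return()
    }
    pf <- per_frame[[fi]]
    card <- vapply(pf$matchings, nrow, numeric(1))
    for (mm in pf$matchings[card == max(card)]) {
      lm <- last_match
      ids_t <- 0
      for (r in seq_len(nrow(mm))) {
        gid <- as.character(pf$g$id[mm[r, 1]])
        hid <- pf$h$id[mm[r, 2]]
        if (!is.null(lm[[gid]]) && lm[[gid]] != hid) ids_t <- ids_t + 1
        lm[[gid]] <- hid
      }
      eval_seq(fi + 1, lm,
               fn + nrow(pf$g) - nrow(mm),
               fp + nrow(pf$h) - nrow(mm),
               ids + ids_t, gtc)
    }
  }
  eval_seq(1, list(), 0, 0, 0, 0)
  best
}

# Tiny deterministic stereo scene builders -----------------------------------

linear_stream <- function(n_targets = 5, n_frames = 60, step = 4,
                          w = 18, h = 18, y_gap = 60) {
  do.call(rbind, lapply(seq_len(n_targets), function(k) {
    bounding_boxes(frame = seq_len(n_frames) - 1L,
                   x = 10 + step * (seq_len(n_frames) - 1L),
                   y = k * y_gap, w = w, h = h, conf = 1,
                   source = "fused", id = k)
  }))
}
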