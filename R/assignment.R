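#' Optimal linear assignment
#'
#' Exact minimum-cost bipartite assignment (the problem the Hungarian
#' algorithm solves), computed by dynamic programming over column subsets.
#' Exact, and fast for the small cost matrices that arise when tracking a
#' handful of targets: complexity is `O(n * 2^m * m)` with `m` the smaller
#' dimension.
#'
#' Entries with non-finite cost are forbidden pairs. When the matrix is
#' rectangular, `min(nrow, ncol)` pairs are assigned (the rest are left
#' unassigned); if forbidden pairs make that infeasible, the largest
#' feasible number of pairs is assigned at minimal cost.
#'
#' @param cost numeric cost matrix.
#' @return integer vector of length `nrow(cost)`; element `i` is the column
#'   assigned to row `i`, or `NA` if unassigned.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n0 <- nrow(cost); m0 <- ncol(cost)
  if (n0 == 0 || m0 == 0) return(rep(NA_integer_, n0))
  transposed <- m0 > n0
  if (transposed) cost <- t(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (m > 16) stop("assignment problem too large for the subset solver")
  k <- m                     # pairs to place (m <= n here)
  nmask <- bitwShiftL(1L, m)
  states <- 0:(nmask - 1L)
  popcnt <- integer(nmask)
  for (j in seq_len(m)) popcnt <- popcnt +
      bitwAnd(bitwShiftR(states, j - 1L), 1L)

  prev <- rep(Inf, nmask)
  prev[1] <- 0
  choice <- vector("list", n)
  for (i in seq_len(n)) {
    cur <- rep(Inf, nmask)
    ch <- rep(NA_integer_, nmask)
    ci <- cost[i, ]
    reach <- which(is.finite(prev)) - 1L
    for (s in reach) {
      base <- prev[s + 1L]
      if (base < cur[s + 1L]) {
        cur[s + 1L] <- base          # leave row i unassigned
        ch[s + 1L] <- 0L
      }
      for (j in seq_len(m)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(s, bit) != 0L || !is.finite(ci[j])) next
        ns <- bitwOr(s, bit) + 1L
        v <- base + ci[j]
        if (v < cur[ns]) { cur[ns] <- v; ch[ns] <- j }
      }
    }
    choice[[i]] <- ch
    prev <- cur
  }

  feas <- which(is.finite(prev)) - 1L
  if (length(feas) == 0) return(rep(NA_integer_, n0))
  sizes <- popcnt[feas + 1L]
  feas <- feas[sizes == max(sizes)]
  s <- feas[which.min(prev[feas + 1L])]
  assign <- rep(NA_integer_, n)
  for (i in rev(seq_len(n))) {
    j <- choice[[i]][s + 1L]
    if (!is.na(j) && j > 0L) {
      assign[i] <- j
      s <- bitwAnd(s, bitwNot(bitwShiftL(1L, j - 1L)))
    }
  }
  if (!transposed) return(assign)
  out <- rep(NA_integer_, n0)
  for (i in seq_along(assign))
    if (!is.na(assign[i])) out[assign[i]] <- i
  out
}
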