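# Constant-velocity Kalman filter over box observations, in the classic
# tracking-by-detection parameterisation: state
#   x = (cx, cy, s, r, vx, vy, vs)
# with box center (cx, cy), area s, aspect ratio r = w/h, and rates of the
# first three. The aspect ratio is held constant between updates.

kf_matrices <- function() {
  F <- diag(7)
  F[1, 5] <- 1; F[2, 6] <- 1; F[3, 7] <- 1
  H <- cbind(diag(4), matrix(0, 4, 3))
  R <- diag(c(1, 1, 10, 10))
  P <- diag(c(10, 10, 10, 10, 1e4, 1e4, 1e4))
  Q <- diag(c(1, 1, 1, 0.01, 0.01, 0.01, 1e-4))
  list(F = F, H = H, R = R, P0 = P, Q = Q)
}

box_to_z <- function(box) {
  c(box$x + box$w / 2, box$y + box$h / 2, box$w * box$h, box$w / box$h)
}

z_to_box <- function(z, frame = 0L, conf = 1, source = "fused") {
  s <- max(z[3], 1e-6)
  r <- max(z[4], 1e-6)
  w <- sqrt(s * r)
  h <- s / w
  bounding_boxes(frame = frame, x = z[1] - w / 2, y = z[2] - h / 2,
                 w = w, h = h, conf = min(max(conf, 0), 1), source = source)
}

kf_init <- function(box) {
  m <- kf_matrices()
  x <- c(box_to_z(box), 0, 0, 0)
  list(x = x, P = m$P0, m = m)
}

kf_predict <- function(kf) {
  # keep predicted area positive: zero the area rate if it would go negative
  if (kf$x[3] + kf$x[7] <= 0) kf$x[7] <- 0
  kf$x <- as.numeric(kf$m$F %*% kf$x)
  kf$x[3] <- max(kf$x[3], 1e-6)
  kf$P <- kf$m$F %*% kf$P %*% t(kf$m$F) + kf$m$Q
  kf
}

kf_update <- function(kf, box) {
  z <- box_to_z(box)
  H <- kf$m$H
  y <- z - as.numeric(H %*% kf$x)
  S <- H %*% kf$P %*% t(H) + kf$m$R
  K <- kf$P %*% t(H) %*% solve(S)
  kf$x <- as.numeric(kf$x + K %*% y)
  kf$x[3] <- max(kf$x[3], 1e-6)
  kf$P <- (diag(7) - K %*% H) %*% kf$P
  kf
}

kf_speed <- function(kf) sqrt(kf$x[5]^2 + kf$x[6]^2)
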