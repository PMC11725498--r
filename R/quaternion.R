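# Minimal quaternion toolkit for head-orientation work.
#
# Quaternions are rows of an n x 4 matrix (w, x, y, z), unit norm.
# Euler convention throughout the package: intrinsic yaw-pitch-roll
# (Z-Y'-X''), angles in degrees, yaw in [-180, 180), pitch in [-90, 90].

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

quat_normalize <- function(q) {
  q <- rbind(q)
  q / sqrt(rowSums(q^2))
}

quat_conj <- function(q) {
  q <- rbind(q)
  q * rep(c(1, -1, -1, -1), each = nrow(q))
}

quat_mul <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  cbind(a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
        a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
        a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
        a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1])
}

# rotate 3-vectors (rows of v) by quaternion(s) q: v' = q v q*
quat_rotate <- function(q, v) {
  q <- rbind(q); v <- rbind(v)
  n <- max(nrow(q), nrow(v))
  if (nrow(q) == 1L) q <- q[rep(1L, n), , drop = FALSE]
  if (nrow(v) == 1L) v <- v[rep(1L, n), , drop = FALSE]
  qv <- cbind(0, v)
  out <- quat_mul(quat_mul(q, qv), quat_conj(q))
  out[, 2:4, drop = FALSE]
}

#' Convert between Euler angles and unit quaternions
#'
#' Intrinsic yaw-pitch-roll (Z-Y'-X'') convention, degrees. Yaw is the
#' absolute heading about the world vertical, which is the quantity the
#' commutator consumes; pitch is elevation of the head axis, roll the bank.
#'
#' @param yaw_deg,pitch_deg,roll_deg Euler angles in degrees (vectorized).
#' @return `quat_from_ypr()`: an n x 4 matrix of unit quaternions
#'   (w, x, y, z).
#' @export
quat_from_ypr <- function(yaw_deg, pitch_deg, roll_deg = 0) {
  n <- max(length(yaw_deg), length(pitch_deg), length(roll_deg))
  y <- rep_len(yaw_deg, n) * DEG2RAD / 2
  p <- rep_len(pitch_deg, n) * DEG2RAD / 2
  r <- rep_len(roll_deg, n) * DEG2RAD / 2
  cy <- cos(y); sy <- sin(y); cp <- cos(p); sp <- sin(p)
  cr <- cos(r); sr <- sin(r)
  cbind(cy * cp * cr + sy * sp * sr,
        cy * cp * sr - sy * sp * cr,
        cy * sp * cr + sy * cp * sr,
        sy * cp * cr - cy * sp * sr)
}

#' @param q An n x 4 matrix (or length-4 vector) of unit quaternions.
#' @return `quat_to_ypr()`: a data frame with `yaw_deg` in \[-180, 180),
#'   `pitch_deg` in \[-90, 90\], `roll_deg` in \[-180, 180).
#' @rdname quat_from_ypr
#' @export
quat_to_ypr <- function(q) {
  q <- quat_normalize(q)
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  sinp <- pmin(1, pmax(-1, 2 * (w * y - z * x)))
  yaw <- atan2(2 * (w * z + x * y), 1 - 2 * (y^2 + z^2)) * RAD2DEG
  pitch <- asin(sinp) * RAD2DEG
  roll <- atan2(2 * (w * x + y * z), 1 - 2 * (x^2 + y^2)) * RAD2DEG
  data.frame(yaw_deg = wrap180(yaw), pitch_deg = pitch,
             roll_deg = wrap180(roll))
}

# spherical linear interpolation between paired rows of q1, q2 at fraction t
quat_slerp <- function(q1, q2, t) {
  q1 <- quat_normalize(q1); q2 <- quat_normalize(q2)
  n <- max(nrow(q1), nrow(q2), length(t))
  if (nrow(q1) == 1L) q1 <- q1[rep(1L, n), , drop = FALSE]
  if (nrow(q2) == 1L) q2 <- q2[rep(1L, n), , drop = FALSE]
  t <- rep_len(t, n)
  d <- rowSums(q1 * q2)
  flip <- d < 0                      # take the short arc
  q2[flip, ] <- -q2[flip, ]
  d <- abs(d)
  d <- pmin(1, d)
  theta <- acos(d)
  s <- sin(theta)
  w1 <- ifelse(s < 1e-8, 1 - t, sin((1 - t) * theta) / s)
  w2 <- ifelse(s < 1e-8, t, sin(t * theta) / s)
  quat_normalize(q1 * w1 + q2 * w2)
}

# wrap degrees into [-180, 180)
wrap180 <- function(deg) ((deg + 180) %% 360) - 180

# wrap degrees into [0, 360)
wrap360 <- function(deg) deg %% 360
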