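#' Lighthouse base-station pose
#'
#' A fixed tracking station that sweeps laser planes through the arena; its
#' pose maps sweep angles to world-frame rays. The station's optical axis
#' is local +y, azimuth rotates about local +z (vertical), elevation about
#' local +x.
#'
#' @param station_id Integer id.
#' @param position 3-vector, meters, world frame (right-handed, z up,
#'   origin at arena center).
#' @param orientation Unit quaternion (w, x, y, z) of the station in the
#'   world frame.
#' @param sweep_period_s Rotation period of the sweep (default 1/60 s).
#' @return A `station_pose` object.
#' @export
station_pose <- function(station_id, position, orientation = c(1, 0, 0, 0),
                         sweep_period_s = 1 / 60) {
  stopifnot(length(position) == 3, length(orientation) == 4,
            sweep_period_s > 0)
  nrm <- sqrt(sum(orientation^2))
  if (abs(nrm - 1) > 1e-6) stop("orientation must be a unit quaternion")
  structure(list(station_id = as.integer(station_id),
                 position = as.double(position),
                 orientation = as.double(orientation) / nrm,
                 sweep_period_s = sweep_period_s),
            class = "station_pose")
}

#' A default two-station rig
#'
#' Two stations 2 m apart, 2 m high, pitched down toward the arena center —
#' a conventional small-room setup. Convenience for simulations and tests.
#'
#' @param sweep_period_s Sweep period, default 1/60 s.
#' @return List of two [station_pose()] objects.
#' @export
default_stations <- function(sweep_period_s = 1 / 60) {
  aim <- function(from) {
    # orient local +y (boresight) toward the arena origin, local x kept
    # horizontal: yaw about world z, then tilt about local x
    d <- -from / sqrt(sum(from^2))
    alpha <- atan2(-d[1], d[2])
    beta <- asin(pmin(1, pmax(-1, d[3])))
    qz <- c(cos(alpha / 2), 0, 0, sin(alpha / 2))
    qx <- c(cos(beta / 2), sin(beta / 2), 0, 0)
    quat_mul(qz, qx)[1, ]
  }
  p1 <- c(-1, -1, 2); p2 <- c(1, 1, 2)
  list(station_pose(1L, p1, aim(p1), sweep_period_s),
       station_pose(2L, p2, aim(p2), sweep_period_s))
}

#' Convert sweep-pulse offsets to sweep angles
#'
#' A rotating laser plane crosses the sensor at a time offset within the
#' sweep period; the angle is `2 * pi * offset / period`, mapped to
#' (-pi, pi].
#'
#' @param az_offset_s,el_offset_s Pulse offsets within one period, seconds,
#'   in \[0, period).
#' @param sweep_period_s Sweep period in seconds.
#' @return Data frame `azimuth_rad`, `elevation_rad` in (-pi, pi].
#' @export
sweep_to_angles <- function(az_offset_s, el_offset_s, sweep_period_s) {
  if (any(az_offset_s < 0 | az_offset_s >= sweep_period_s) ||
      any(el_offset_s < 0 | el_offset_s >= sweep_period_s)) {
    stop_tethersim("domain", "pulse offsets must lie in [0, sweep period)")
  }
  to_angle <- function(off) {
    a <- 2 * pi * off / sweep_period_s
    ifelse(a > pi, a - 2 * pi, a)
  }
  data.frame(azimuth_rad = to_angle(az_offset_s),
             elevation_rad = to_angle(el_offset_s))
}

# station-frame unit direction for given azimuth/elevation
angles_to_direction <- function(az, el) {
  cbind(sin(az) * cos(el), cos(az) * cos(el), sin(el))
}

#' Triangulate a 3D position from per-station sweep angles
#'
#' Each station's (azimuth, elevation) defines a world-frame ray from the
#' station; with two stations the estimate is the midpoint of the shortest
#' segment between the rays, and with more it is the least-squares closest
#' point. The residual is the ray miss distance (for two stations, the
#' length of that shortest segment; generally the RMS orthogonal distance
#' from the estimate to the rays, scaled to match in the two-ray case).
#'
#' @param angles A data frame (or list of rows) with `station_id`,
#'   `azimuth_rad`, `elevation_rad` — one row per station.
#' @param stations List of [station_pose()] objects covering those ids.
#' @param min_ray_angle_deg Rays closer than this to parallel raise an
#'   ill-conditioned error (default 0.5 degrees; two-station case).
#' @return List with `position` (3-vector, m) and `residual_m`.
#' @export
triangulate <- function(angles, stations, min_ray_angle_deg = 0.5) {
  angles <- as.data.frame(angles)
  m <- nrow(angles)
  if (m < 2) {
    stop_tethersim("insufficient_data",
                   "triangulation needs at least two stations")
  }
  by_id <- setNames(stations, vapply(stations, `[[`, integer(1), "station_id"))
  origins <- matrix(0, m, 3); dirs <- matrix(0, m, 3)
  for (i in seq_len(m)) {
    st <- by_id[[as.character(angles$station_id[i])]]
    if (is.null(st)) stop_tethersim("unknown_device", "unknown station id")
    d_local <- angles_to_direction(angles$azimuth_rad[i],
                                   angles$elevation_rad[i])
    dirs[i, ] <- quat_rotate(st$orientation, d_local)
    origins[i, ] <- st$position
  }
  if (m == 2) {
    cosang <- abs(sum(dirs[1, ] * dirs[2, ]))
    if (cosang > cos(min_ray_angle_deg * DEG2RAD)) {
      stop_tethersim("ill_conditioned",
                     "rays are near-parallel; cannot triangulate")
    }
  }
  # least squares: sum_i (I - d_i d_i^T) x = sum_i (I - d_i d_i^T) o_i
  A <- matrix(0, 3, 3); b <- numeric(3)
  for (i in seq_len(m)) {
    P <- diag(3) - tcrossprod(dirs[i, ])
    A <- A + P
    b <- b + P %*% origins[i, ]
  }
  if (rcond(A) < 1e-10) {
    stop_tethersim("ill_conditioned", "degenerate ray geometry")
  }
  x <- as.vector(solve(A, b))
  # orthogonal distance from x to each ray
  dd <- vapply(seq_len(m), function(i) {
    v <- x - origins[i, ]
    sqrt(max(0, sum(v^2) - sum(v * dirs[i, ])^2))
  }, numeric(1))
  residual <- if (m == 2) sum(dd) else sqrt(mean(dd^2))
  list(position = x, residual_m = residual)
}

#' Triangulate a whole event table into a position track
#'
#' Groups [generate_lighthouse_events()] output by trajectory sample,
#' converts offsets to angles, and triangulates every sample seen by at
#' least two stations.
#'
#' @param events Event data frame from [generate_lighthouse_events()].
#' @param stations List of [station_pose()] objects.
#' @return Data frame `time_s`, `sample`, `x_m`, `y_m`, `z_m`,
#'   `residual_m`.
#' @export
track_positions <- function(events, stations) {
  period <- stations[[1]]$sweep_period_s
  ang <- sweep_to_angles(events$az_offset_s, events$el_offset_s, period)
  events$azimuth_rad <- ang$azimuth_rad
  events$elevation_rad <- ang$elevation_rad
  keep <- split(seq_len(nrow(events)), events$sample)
  rows <- lapply(keep, function(idx) {
    if (length(idx) < 2) return(NULL)
    tri <- triangulate(events[idx, c("station_id", "azimuth_rad",
                                     "elevation_rad")], stations)
    data.frame(time_s = events$time_s[idx[1]],
               sample = events$sample[idx[1]],
               x_m = tri$position[1], y_m = tri$position[2],
               z_m = tri$position[3], residual_m = tri$residual_m)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(time_s = numeric(0), sample = integer(0),
                      x_m = numeric(0), y_m = numeric(0), z_m = numeric(0),
                      residual_m = numeric(0))
  }
  rownames(out) <- NULL
  out[order(out$time_s), ]
}

#' Fuse optical position with inertial orientation
#'
#' Resamples both modalities onto a uniform grid covering the overlap of
#' their time ranges: positions by linear interpolation, orientations by
#' spherical interpolation between bracketing samples. Grid points with no
#' optical sample within `max_gap_s` are flagged `imu_only` and hold the
#' last optical position. Yaw/pitch/roll always come from the inertial
#' stream (the absolute sensor), which is what drives the commutator.
#'
#' @param optical Data frame `time_s`, `x_m`, `y_m`, `z_m`, optionally
#'   `residual_m`.
#' @param imu Data frame `time_s` plus quaternion columns `qw`,`qx`,`qy`,`qz`.
#' @param output_rate_hz Output grid rate, default 100 Hz.
#' @param max_gap_s Optical dropout gap, default 0.2 s.
#' @return Data frame `time_s`, `x_m`, `y_m`, `z_m`, `yaw_deg`,
#'   `pitch_deg`, `roll_deg`, `position_source` ("optical" or "imu_only"),
#'   `residual_m`.
#' @export
fuse_pose <- function(optical, imu, output_rate_hz = 100, max_gap_s = 0.2) {
  if (nrow(optical) == 0 || nrow(imu) == 0) {
    return(data.frame(time_s = numeric(0), x_m = numeric(0),
                      y_m = numeric(0), z_m = numeric(0),
                      yaw_deg = numeric(0), pitch_deg = numeric(0),
                      roll_deg = numeric(0),
                      position_source = character(0),
                      residual_m = numeric(0)))
  }
  if (is.unsorted(optical$time_s, strictly = TRUE) ||
      is.unsorted(imu$time_s, strictly = TRUE)) {
    stop_tethersim("ordering", "input timestamps must be strictly increasing")
  }
  t0 <- max(min(optical$time_s), min(imu$time_s))
  t1 <- min(max(optical$time_s), max(imu$time_s))
  if (t1 < t0) stop_tethersim("ordering", "input time ranges do not overlap")
  grid <- seq(ceiling(t0 * output_rate_hz), floor(t1 * output_rate_hz)) /
    output_rate_hz
  interp <- function(y) approx(optical$time_s, y, xout = grid, rule = 2)$y
  px <- interp(optical$x_m); py <- interp(optical$y_m)
  pz <- interp(optical$z_m)
  res <- if ("residual_m" %in% names(optical)) {
    interp(optical$residual_m)
  } else rep(0, length(grid))
  # dropout: nearest optical sample farther than max_gap_s
  lo <- findInterval(grid, optical$time_s)
  d_prev <- ifelse(lo >= 1, grid - optical$time_s[pmax(lo, 1L)], Inf)
  d_next <- ifelse(lo < nrow(optical),
                   optical$time_s[pmin(lo + 1L, nrow(optical))] - grid, Inf)
  gap <- pmin(d_prev, d_next) > max_gap_s
  if (any(gap)) {
    hold <- pmax(lo, 1L)   # hold last seen optical fix
    px[gap] <- optical$x_m[hold[gap]]
    py[gap] <- optical$y_m[hold[gap]]
    pz[gap] <- optical$z_m[hold[gap]]
  }
  # slerp orientation between bracketing imu samples
  qi <- as.matrix(imu[, c("qw", "qx", "qy", "qz")])
  j <- pmin(pmax(findInterval(grid, imu$time_s), 1L), nrow(imu) - 1L)
  if (nrow(imu) == 1L) {
    q <- qi[rep(1L, length(grid)), , drop = FALSE]
  } else {
    tfrac <- (grid - imu$time_s[j]) / (imu$time_s[j + 1L] - imu$time_s[j])
    tfrac <- pmin(1, pmax(0, tfrac))
    q <- quat_slerp(qi[j, , drop = FALSE], qi[j + 1L, , drop = FALSE], tfrac)
  }
  ypr <- quat_to_ypr(q)
  data.frame(time_s = grid, x_m = px, y_m = py, z_m = pz,
             yaw_deg = ypr$yaw_deg, pitch_deg = ypr$pitch_deg,
             roll_deg = ypr$roll_deg,
             position_source = ifelse(gap, "imu_only", "optical"),
             residual_m = res)
}

#' Read or write the pose CSV interchange format
#'
#' Columns: `time_s, x_m, y_m, z_m, yaw_deg, pitch_deg, roll_deg,
#' position_source, residual_m`. Consumed by the commutation and behavior
#' modules.
#'
#' @param pose Pose data frame (as from [fuse_pose()]).
#' @param path File path.
#' @export
write_pose_csv <- function(pose, path) {
  utils::write.csv(pose, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pose_csv
#' @export
read_pose_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
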