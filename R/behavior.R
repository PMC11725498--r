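# Behavioral quantification: speed, occupancy/heading histograms, Shannon
# entropy with time-bin block bootstrap, and long-recording activity and
# band-power measures.

# boxcar mean with edge handling by window truncation
boxcar_smooth <- function(x, width) {
  n <- length(x)
  if (width <= 1 || n == 0L) return(x)
  h <- floor(width / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

traj_dt <- function(trajectory) {
  t <- trajectory$time_s
  if (length(t) < 2) stop_tethersim("insufficient_data", "need >= 2 samples")
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-6 * mean(dt)) {
    stop("trajectory must be uniformly sampled; resample first")
  }
  mean(dt)
}

#' 3D running speed from a uniformly sampled trajectory
#'
#' Centered-difference 3D speed, boxcar-smoothed; edge samples use
#' one-sided differences and truncated smoothing windows.
#'
#' @param trajectory Data frame with `time_s`, `x_m`, `y_m`, `z_m` on a
#'   uniform grid (100 Hz in the standard pipeline).
#' @param smoothing_window_s Boxcar width in seconds, default 0.25.
#' @return Numeric speed series (m/s), same length as the input.
#' @export
compute_speed <- function(trajectory, smoothing_window_s = 0.25) {
  n <- nrow(trajectory)
  if (n < 3) stop_tethersim("insufficient_data", "need >= 3 samples")
  dt <- traj_dt(trajectory)
  p <- as.matrix(trajectory[, c("x_m", "y_m", "z_m")])
  v <- (p[c(2:n, n), ] - p[c(1, 1:(n - 1)), ]) /
    c(dt, rep(2 * dt, n - 2), dt)
  speed <- sqrt(rowSums(v^2))
  boxcar_smooth(speed, max(1L, round(smoothing_window_s / dt)))
}

new_occupancy_grid <- function(counts, n_bins, extent, excluded_bins,
                               dwell_seconds_total, axes, clipped = 0L) {
  structure(list(counts = counts, n_bins = n_bins, extent = extent,
                 excluded_bins = excluded_bins,
                 dwell_seconds_total = dwell_seconds_total,
                 axes = axes, clipped = clipped),
            class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf(
    "<occupancy_grid: %dx%d bins (%s), %s counts, %d excluded bin(s), %.1f s dwell>\n",
    x$n_bins[1], x$n_bins[2], paste(x$axes, collapse = " x "),
    format(sum(x$counts), big.mark = ","), length(x$excluded_bins),
    x$dwell_seconds_total))
  invisible(x)
}

bin_index_2d <- function(u, v, n_bins, extent, clip = FALSE) {
  bu <- findInterval(u, seq(extent[[1]][1], extent[[1]][2],
                            length.out = n_bins[1] + 1L),
                     rightmost.closed = TRUE)
  bv <- findInterval(v, seq(extent[[2]][1], extent[[2]][2],
                            length.out = n_bins[2] + 1L),
                     rightmost.closed = TRUE)
  out_of_range <- bu < 1 | bu > n_bins[1] | bv < 1 | bv > n_bins[2]
  n_clip <- sum(out_of_range)
  if (clip) {
    bu <- pmin(pmax(bu, 1L), n_bins[1])
    bv <- pmin(pmax(bv, 1L), n_bins[2])
    ok <- rep(TRUE, length(bu))
  } else {
    ok <- !out_of_range
  }
  list(cell = (bv - 1L) * n_bins[1] + bu, ok = ok, n_clipped = n_clip)
}

#' Spatial occupancy histogram
#'
#' Bins moving samples (speed at or above the stationary threshold) into an
#' x-y grid spanning the arena — 20 x 20 by default. With
#' `exclude_home = TRUE`, the single highest-count bin (the home position,
#' where dwell is elevated) is marked excluded so it carries no probability
#' mass in entropy computations. The processing order is fixed: stationary
#' filter, then histogram, then home-bin exclusion, then normalization.
#'
#' @param trajectory Uniformly sampled data frame with `time_s`, `x_m`,
#'   `y_m`, `z_m`.
#' @param n_bins Integer 2-vector, default `c(20, 20)`.
#' @param extent List of x and y ranges; default the 1.6 m arena bounding
#'   box `[-0.8, 0.8]` on both axes.
#' @param stationary_speed_threshold Speed below which samples are treated
#'   as stationary and excluded (m/s; default 0.02 on the 0.25-s-smoothed
#'   speed).
#' @param exclude_home Exclude the argmax bin (default TRUE).
#' @param speed Optional precomputed speed series (else [compute_speed()]
#'   is called).
#' @return An `occupancy_grid`; attribute `empty` is TRUE when every
#'   sample was stationary.
#' @export
occupancy_histogram <- function(trajectory, n_bins = c(20L, 20L),
                                extent = list(x = c(-0.8, 0.8),
                                              y = c(-0.8, 0.8)),
                                stationary_speed_threshold = 0.02,
                                exclude_home = TRUE, speed = NULL) {
  dt <- traj_dt(trajectory)
  if (is.null(speed)) speed <- compute_speed(trajectory)
  moving <- speed >= stationary_speed_threshold
  b <- bin_index_2d(trajectory$x_m[moving], trajectory$y_m[moving],
                    n_bins, extent, clip = TRUE)
  counts <- matrix(tabulate(b$cell, prod(n_bins)),
                   nrow = n_bins[1], ncol = n_bins[2])
  excluded <- integer(0)
  if (exclude_home && sum(counts) > 0) excluded <- which.max(counts)
  g <- new_occupancy_grid(counts, n_bins, extent, excluded,
                          dwell_seconds_total = sum(moving) * dt,
                          axes = c("x_m", "y_m"), clipped = b$n_clipped)
  attr(g, "empty") <- !any(moving)
  g
}

#' Heading (yaw x pitch) histogram
#'
#' A 40 x 40 histogram over 0-360 degrees yaw and +/-45 degrees pitch.
#' Binning is linear (no circular merge of the yaw ends); pitch outside
#' +/-45 degrees is clipped into the end bins and counted in `$clipped`.
#'
#' @param trajectory Data frame with `yaw_deg` in \[0, 360) and
#'   `pitch_deg`.
#' @param n_bins Integer 2-vector, default `c(40, 40)`.
#' @return An `occupancy_grid` over (yaw, pitch).
#' @export
heading_histogram <- function(trajectory, n_bins = c(40L, 40L)) {
  dt <- tryCatch(traj_dt(trajectory), error = function(e) NA_real_)
  extent <- list(yaw = c(0, 360), pitch = c(-45, 45))
  b <- bin_index_2d(trajectory$yaw_deg, trajectory$pitch_deg, n_bins,
                    extent, clip = TRUE)
  counts <- matrix(tabulate(b$cell, prod(n_bins)),
                   nrow = n_bins[1], ncol = n_bins[2])
  dwell <- if (is.na(dt)) NA_real_ else nrow(trajectory) * dt
  new_occupancy_grid(counts, n_bins, extent, integer(0), dwell,
                     axes = c("yaw_deg", "pitch_deg"), clipped = b$n_clipped)
}

#' Shannon entropy of a dwell distribution
#'
#' `H = -sum(p * log2(p))` over included (non-excluded) bins with
#' `p = count / total` and `0 log 0 := 0`. With `normalized = TRUE` the
#' entropy is divided by `log2(number of included bins)`, the entropy of
#' the uniform distribution with the same bin count, giving a value in
#' \[0, 1\].
#'
#' @param grid An `occupancy_grid` (or a plain count matrix).
#' @param normalized Normalize by the uniform-distribution entropy.
#' @return Entropy in bits (or a dimensionless ratio if normalized).
#' @export
shannon_entropy_bits <- function(grid, normalized = FALSE) {
  if (inherits(grid, "occupancy_grid")) {
    counts <- grid$counts
    counts[grid$excluded_bins] <- 0
    n_included <- length(counts) - length(grid$excluded_bins)
  } else {
    counts <- grid
    n_included <- length(counts)
  }
  total <- sum(counts)
  if (total <= 0) {
    stop_tethersim("undefined_entropy", "no counts in included bins")
  }
  p <- counts[counts > 0] / total
  h <- -sum(p * log2(p))
  if (normalized) h <- h / log2(n_included)
  h
}

#' Block-bootstrap entropy with time-bin resampling
#'
#' Partitions the trajectory into contiguous time bins (~1 min), resamples
#' bins with replacement, rebuilds the histogram for each replicate —
#' re-applying the stationary filter and home-bin exclusion — and computes
#' both raw and normalized entropy. Returns the replicate median and the
#' 2.5/97.5 percentile bounds; fully reproducible from the seed.
#'
#' @param trajectory Uniformly sampled trajectory data frame.
#' @param type `"occupancy"` (spatial, speed-filtered) or `"heading"`.
#' @param n_bins,extent,stationary_speed_threshold,exclude_home Passed to
#'   the histogram step (defaults as in [occupancy_histogram()] /
#'   [heading_histogram()]).
#' @param time_bin_s Time-bin length, default exactly 60 s; a truncated
#'   final bin is dropped.
#' @param n_boot Number of bootstrap replicates, default 1000.
#' @param seed Integer seed.
#' @return List with `raw` and `normalized`, each
#'   `list(median, ci_low, ci_high)`, plus `n_time_bins`, `n_boot`,
#'   `seed`, and the replicate vectors in `replicates`.
#' @export
bootstrap_entropy <- function(trajectory, type = c("occupancy", "heading"),
                              n_bins = NULL, extent = NULL,
                              stationary_speed_threshold = 0.02,
                              exclude_home = TRUE, time_bin_s = 60,
                              n_boot = 1000L, seed = 1L) {
  type <- match.arg(type)
  t <- trajectory$time_s
  dt <- traj_dt(trajectory)
  bin_id <- floor((t - t[1]) / time_bin_s) + 1L
  n_full <- floor((t[length(t)] - t[1] + dt) / time_bin_s)
  if (n_full < 2) {
    stop_tethersim("insufficient_data",
                   "need at least two complete time bins")
  }
  keep_t <- bin_id <= n_full
  if (type == "occupancy") {
    if (is.null(n_bins)) n_bins <- c(20L, 20L)
    if (is.null(extent)) extent <- list(x = c(-0.8, 0.8), y = c(-0.8, 0.8))
    speed <- compute_speed(trajectory)
    incl <- keep_t & speed >= stationary_speed_threshold
    b <- bin_index_2d(trajectory$x_m[incl], trajectory$y_m[incl],
                      n_bins, extent, clip = TRUE)
  } else {
    if (is.null(n_bins)) n_bins <- c(40L, 40L)
    extent <- list(yaw = c(0, 360), pitch = c(-45, 45))
    exclude_home <- FALSE
    incl <- keep_t
    b <- bin_index_2d(trajectory$yaw_deg[incl], trajectory$pitch_deg[incl],
                      n_bins, extent, clip = TRUE)
  }
  n_cells <- prod(n_bins)
  # per-time-bin cell count matrix: replicate histograms are row sums
  tb <- bin_id[incl]
  M <- matrix(tabulate((tb - 1L) * n_cells + b$cell, n_full * n_cells),
              nrow = n_full, ncol = n_cells, byrow = TRUE)
  set.seed(seed)
  raw_rep <- numeric(n_boot); norm_rep <- numeric(n_boot)
  for (i in seq_len(n_boot)) {
    rows <- sample.int(n_full, n_full, replace = TRUE)
    counts <- colSums(M[rows, , drop = FALSE])
    n_incl_bins <- n_cells
    if (exclude_home && sum(counts) > 0) {
      counts[which.max(counts)] <- 0
      n_incl_bins <- n_cells - 1L
    }
    total <- sum(counts)
    if (total == 0) { raw_rep[i] <- NA; norm_rep[i] <- NA; next }
    p <- counts[counts > 0] / total
    h <- -sum(p * log2(p))
    raw_rep[i] <- h
    norm_rep[i] <- h / log2(n_incl_bins)
  }
  ci <- function(x) {
    q <- stats::quantile(x, c(0.5, 0.025, 0.975), na.rm = TRUE,
                         names = FALSE)
    list(median = q[1], ci_low = q[2], ci_high = q[3])
  }
  list(raw = ci(raw_rep), normalized = ci(norm_rep),
       n_time_bins = n_full, n_boot = n_boot, seed = seed,
       replicates = list(raw = raw_rep, normalized = norm_rep))
}

#' Band power over time windows
#'
#' Zero-phase band-pass (frequency-domain brick-wall mask) per band, then
#' mean squared amplitude in non-overlapping windows. The defaults are the
#' 6-10 Hz and 30-50 Hz bands over 10-s windows used to follow awake/sleep
#' structure in long recordings.
#'
#' @param x Numeric signal.
#' @param sample_rate_hz Sample rate (Hz).
#' @param bands List of `c(low, high)` band edges in Hz.
#' @param window_s Window length in seconds, default 10.
#' @return Data frame `window`, `t_start_s`, `band`, `power`.
#' @export
band_power <- function(x, sample_rate_hz,
                       bands = list(c(6, 10), c(30, 50)), window_s = 10) {
  n <- length(x)
  win <- round(window_s * sample_rate_hz)
  if (n < win) stop_tethersim("insufficient_data",
                              "signal shorter than one window")
  for (b in bands) {
    if (max(b) >= sample_rate_hz / 2) {
      stop_tethersim("domain", "band edge at or above Nyquist")
    }
  }
  n_win <- floor(n / win)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * sample_rate_hz / n
  f_fold <- pmin(f, sample_rate_hz - f)
  out <- vector("list", length(bands))
  for (k in seq_along(bands)) {
    mask <- f_fold >= bands[[k]][1] & f_fold <= bands[[k]][2]
    xf <- Re(stats::fft(X * mask, inverse = TRUE)) / n
    pw <- vapply(seq_len(n_win), function(w) {
      mean(xf[((w - 1) * win + 1):(w * win)]^2)
    }, numeric(1))
    out[[k]] <- data.frame(window = seq_len(n_win),
                           t_start_s = (seq_len(n_win) - 1) * window_s,
                           band = sprintf("%g-%g Hz", bands[[k]][1],
                                          bands[[k]][2]),
                           power = pw)
  }
  do.call(rbind, out)
}

#' Activity level from head acceleration
#'
#' Euclidean norm of the 3D acceleration vector, boxcar-smoothed over 1-s
#' blocks and decimated to 1 Hz.
#'
#' @param acc Numeric matrix, samples x 3 (acceleration components).
#' @param sample_rate_hz Sample rate of `acc`.
#' @return Data frame `time_s` (block starts), `activity`.
#' @export
activity_level <- function(acc, sample_rate_hz) {
  acc <- rbind(acc)
  nrm <- sqrt(rowSums(acc^2))
  blk <- max(1L, round(sample_rate_hz))
  n_blk <- floor(length(nrm) / blk)
  if (n_blk == 0L) {
    return(data.frame(time_s = 0, activity = mean(nrm)))
  }
  act <- vapply(seq_len(n_blk), function(b) {
    mean(nrm[((b - 1) * blk + 1):(b * blk)])
  }, numeric(1))
  data.frame(time_s = seq_len(n_blk) - 1, activity = act)
}

#' Yaw range conversions
#'
#' Heading histograms use yaw in \[0, 360); commutation uses \[-180, 180).
#'
#' @param deg Angles in degrees.
#' @return Converted angles.
#' @export
yaw_to_360 <- function(deg) wrap360(deg)

#' @rdname yaw_to_360
#' @export
yaw_to_180 <- function(deg) wrap180(deg)
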