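#' Simulated extracellular recording device
#'
#' Configuration for a seeded generator that emulates a multi-channel
#' bioamplifier/digitizer as a frame producer: Gaussian noise plus
#' template-shaped spikes at Poisson times, quantized to signed 16-bit
#' counts. The generator exists so the closed-loop and link machinery can
#' be exercised, with ground truth, without hardware.
#'
#' @param n_channels Number of channels (>= 1).
#' @param sample_rate_hz Sample rate, default 30000 (spike band).
#' @param noise_sd_uV Noise standard deviation in microvolts.
#' @param spike_amplitude_uV Spike peak amplitude in microvolts; negative
#'   for the usual negative-going extracellular deflection.
#' @param spike_rate_hz Poisson spike rate per channel (Hz).
#' @param spike_template Waveform shape with unit peak magnitude; default a
#'   1-ms biphasic shape (30 samples at 30 kHz). Detection code must not
#'   depend on this exact shape.
#' @param adc_uV_per_count ADC scale, microvolts per count.
#' @param seed Integer seed; the generator is deterministic given
#'   (config, seed).
#' @return An `ephys_sim_config` object.
#' @export
ephys_sim_config <- function(n_channels = 16L, sample_rate_hz = 30000,
                             noise_sd_uV = 10, spike_amplitude_uV = -300,
                             spike_rate_hz = 2,
                             spike_template = default_spike_template(),
                             adc_uV_per_count = 0.195, seed = 1L) {
  stopifnot(n_channels >= 1, sample_rate_hz > 0, noise_sd_uV >= 0,
            spike_rate_hz >= 0, adc_uV_per_count > 0)
  structure(list(n_channels = as.integer(n_channels),
                 sample_rate_hz = sample_rate_hz,
                 noise_sd_uV = noise_sd_uV,
                 spike_amplitude_uV = spike_amplitude_uV,
                 spike_rate_hz = spike_rate_hz,
                 # normalize by the signed peak so spike_amplitude_uV is the
                 # true signed peak of the injected waveform
                 spike_template = spike_template /
                   spike_template[which.max(abs(spike_template))],
                 adc_uV_per_count = adc_uV_per_count,
                 seed = as.integer(seed)),
            class = "ephys_sim_config")
}

#' @rdname ephys_sim_config
#' @param n_samples Template length in samples (1 ms at 30 kHz by default).
#' @export
default_spike_template <- function(n_samples = 30L) {
  tt <- seq(0, 1, length.out = n_samples)
  # biphasic: fast negative lobe, slower positive rebound, unit peak
  w <- -exp(-((tt - 0.2) / 0.12)^2) + 0.45 * exp(-((tt - 0.55) / 0.22)^2)
  w / max(abs(w))
}

#' Generate simulated ephys frames with ground truth
#'
#' One frame per sample period carrying `n_channels` interleaved signed
#' 16-bit little-endian counts. Spikes are placed at Poisson times per
#' channel (or at explicitly supplied times) and shaped by the template;
#' counts beyond the 16-bit range are clipped and counted.
#'
#' @param config An [ephys_sim_config()].
#' @param duration_s Duration in seconds (> 0).
#' @param spike_times Optional explicit spike times: a numeric vector
#'   (applied to channel 1) or a data frame with `channel`, `time_s`.
#'   Overrides the Poisson process.
#' @param device_id Device id for the emitted frames (default 1).
#' @return A list: `frames` ([frame_stream()], timestamps 0..n-1 in sample
#'   ticks), `counts` (n x n_channels integer matrix), `spike_times`
#'   (data frame `channel`, `time_s` — the ground truth), `n_saturated`
#'   (clipped sample count), and `config`.
#' @export
generate_ephys_frames <- function(config, duration_s, spike_times = NULL,
                                  device_id = 1L) {
  stopifnot(inherits(config, "ephys_sim_config"), duration_s > 0)
  fs <- config$sample_rate_hz
  n <- max(1L, round(duration_s * fs))
  nch <- config$n_channels
  set.seed(config$seed)
  noise_counts <- config$noise_sd_uV / config$adc_uV_per_count
  x <- matrix(if (noise_counts > 0) rnorm(n * nch, 0, noise_counts) else 0,
              nrow = n, ncol = nch)
  if (is.null(spike_times)) {
    spike_times <- do.call(rbind, lapply(seq_len(nch), function(ch) {
      k <- rpois(1, config$spike_rate_hz * duration_s)
      if (k == 0) return(NULL)
      data.frame(channel = ch, time_s = sort(runif(k, 0, duration_s)))
    }))
    if (is.null(spike_times)) {
      spike_times <- data.frame(channel = integer(0), time_s = numeric(0))
    }
  } else if (is.numeric(spike_times)) {
    spike_times <- data.frame(channel = 1L, time_s = as.double(spike_times))
  }
  tpl <- config$spike_template * config$spike_amplitude_uV /
    config$adc_uV_per_count
  lt <- length(tpl)
  if (nrow(spike_times)) {
    for (i in seq_len(nrow(spike_times))) {
      s0 <- round(spike_times$time_s[i] * fs) + 1L
      if (s0 > n) next
      idx <- s0:min(n, s0 + lt - 1L)
      x[idx, spike_times$channel[i]] <-
        x[idx, spike_times$channel[i]] + tpl[seq_along(idx)]
    }
  }
  x <- round(x)
  n_sat <- sum(x > 32767 | x < -32768)
  x[x > 32767] <- 32767
  x[x < -32768] <- -32768
  storage.mode(x) <- "integer"
  bytes <- writeBin(as.vector(t(x)), raw(), size = 2L, endian = "little")
  payloads <- split(bytes, rep(seq_len(n), each = 2L * nch))
  names(payloads) <- NULL
  frames <- frame_stream(rep(as.double(device_id), n), seq_len(n) - 1,
                         payloads)
  list(frames = frames, counts = x, spike_times = spike_times,
       n_saturated = n_sat, config = config)
}

#' Decode ephys frame payloads back to a count matrix
#'
#' @param frames A [frame_stream()] of ephys frames.
#' @param n_channels Channel count.
#' @return Integer matrix, samples x channels.
#' @export
ephys_counts <- function(frames, n_channels) {
  bytes <- unlist(frames$payloads, use.names = FALSE)
  v <- readBin(bytes, "integer", n = length(bytes) / 2L, size = 2L,
               signed = TRUE, endian = "little")
  matrix(v, ncol = n_channels, byrow = TRUE)
}

#' Scripted head-orientation source
#'
#' A segment script for a simulated absolute-orientation (IMU) sensor:
#' piecewise-constant yaw rate, pitch and roll, integrated and emitted as
#' unit quaternions at the sensor rate with optional angular noise.
#'
#' @param segments Data frame with columns `duration_s`,
#'   `yaw_rate_deg_per_s`, `pitch_deg`, `roll_deg`.
#' @param sample_rate_hz Sensor rate, default 100 Hz.
#' @param noise_sd_deg Angular noise SD in degrees applied per axis.
#' @param seed Integer seed.
#' @return An `orientation_script` object.
#' @export
orientation_script <- function(segments, sample_rate_hz = 100,
                               noise_sd_deg = 0, seed = 1L) {
  segments <- as.data.frame(segments)
  need <- c("duration_s", "yaw_rate_deg_per_s", "pitch_deg", "roll_deg")
  if (!all(need %in% names(segments))) {
    stop("segments needs columns: ", paste(need, collapse = ", "))
  }
  stopifnot(all(segments$duration_s > 0), sample_rate_hz > 0,
            noise_sd_deg >= 0)
  structure(list(segments = segments, sample_rate_hz = sample_rate_hz,
                 noise_sd_deg = noise_sd_deg, seed = as.integer(seed)),
            class = "orientation_script")
}

#' Generate orientation frames with ground-truth cumulative yaw
#'
#' Integrates the scripted yaw rate, converts (yaw, pitch, roll) to unit
#' quaternions (intrinsic Z-Y'-X''), adds angular noise, and packs each
#' quaternion as four little-endian float32 values (16-byte payload).
#' The unwrapped ground-truth yaw is returned for commutation tests.
#'
#' @param script An [orientation_script()].
#' @param duration_s Optional duration; default is the script's total.
#' @param device_id Device id for emitted frames (default 2).
#' @param clock_hz Shared clock used for frame timestamps (default 30000).
#' @return A list: `frames`, `time_s`, `quat` (n x 4), `true_yaw_deg`
#'   (unwrapped, noise-free), `yaw_deg`/`pitch_deg`/`roll_deg` (noisy,
#'   wrapped), and `script`.
#' @export
generate_orientation_frames <- function(script, duration_s = NULL,
                                        device_id = 2L, clock_hz = 30000) {
  stopifnot(inherits(script, "orientation_script"))
  fs <- script$sample_rate_hz
  total <- sum(script$segments$duration_s)
  if (is.null(duration_s)) duration_s <- total
  stopifnot(duration_s > 0)
  n <- max(1L, round(duration_s * fs))
  t <- (seq_len(n) - 1) / fs
  seg_end <- cumsum(script$segments$duration_s)
  seg_start <- c(0, seg_end[-length(seg_end)])
  seg_idx <- pmin(findInterval(t, seg_start), nrow(script$segments))
  rate <- script$segments$yaw_rate_deg_per_s[seg_idx]
  # yaw integrates the piecewise-constant rate; beyond the script, hold
  beyond <- t >= total
  rate[beyond] <- 0
  true_yaw <- cumsum(c(0, rate[-n] / fs))
  pitch <- script$segments$pitch_deg[seg_idx]
  roll <- script$segments$roll_deg[seg_idx]
  set.seed(script$seed)
  if (script$noise_sd_deg > 0) {
    yaw_n <- true_yaw + rnorm(n, 0, script$noise_sd_deg)
    pitch_n <- pitch + rnorm(n, 0, script$noise_sd_deg)
    roll_n <- roll + rnorm(n, 0, script$noise_sd_deg)
  } else {
    yaw_n <- true_yaw; pitch_n <- pitch; roll_n <- roll
  }
  q <- quat_from_ypr(yaw_n, pitch_n, roll_n)
  qf <- writeBin(as.vector(t(q)), raw(), size = 4L, endian = "little")
  payloads <- split(qf, rep(seq_len(n), each = 16L))
  names(payloads) <- NULL
  frames <- frame_stream(rep(as.double(device_id), n), round(t * clock_hz),
                         payloads)
  list(frames = frames, time_s = t, quat = q, true_yaw_deg = true_yaw,
       yaw_deg = wrap180(yaw_n), pitch_deg = pitch_n, roll_deg = roll_n,
       script = script)
}

#' Decode orientation frame payloads back to quaternions
#'
#' @param frames A [frame_stream()] of orientation frames.
#' @return An n x 4 quaternion matrix (w, x, y, z).
#' @export
orientation_quats <- function(frames) {
  bytes <- unlist(frames$payloads, use.names = FALSE)
  v <- readBin(bytes, "double", n = length(bytes) / 4L, size = 4L,
               endian = "little")
  matrix(v, ncol = 4L, byrow = TRUE)
}

#' Simulate lighthouse sweep events for a trajectory
#'
#' For every trajectory sample and base station, computes the azimuth and
#' elevation sweep-pulse offsets an ideal spinning-plane station would
#' produce (angle = 2 * pi * offset / sweep period), adds Gaussian timing
#' jitter, and drops samples behind a station or inside occlusion windows.
#'
#' @param trajectory Data frame with `time_s`, `x_m`, `y_m`, `z_m`.
#' @param stations List of [station_pose()] objects (>= 2 for 3D recovery).
#' @param timing_jitter_s Gaussian SD of pulse-time jitter in seconds.
#' @param seed Integer seed.
#' @param occlusions Optional data frame `start_s`, `end_s`: intervals
#'   during which all events are dropped.
#' @return Data frame `time_s`, `sample`, `station_id`, `az_offset_s`,
#'   `el_offset_s`; attribute `visibility` reports per-station counts of
#'   emitted/omitted events.
#' @export
generate_lighthouse_events <- function(trajectory, stations,
                                       timing_jitter_s = 0, seed = 1L,
                                       occlusions = NULL) {
  stopifnot(is.data.frame(trajectory), length(stations) >= 1)
  set.seed(seed)
  pos <- as.matrix(trajectory[, c("x_m", "y_m", "z_m")])
  n <- nrow(pos)
  out <- vector("list", length(stations))
  vis <- data.frame(station_id = integer(0), emitted = integer(0),
                    omitted = integer(0))
  occluded <- rep(FALSE, n)
  if (!is.null(occlusions)) {
    for (i in seq_len(nrow(occlusions))) {
      occluded <- occluded | (trajectory$time_s >= occlusions$start_s[i] &
                                trajectory$time_s <= occlusions$end_s[i])
    }
  }
  for (k in seq_along(stations)) {
    st <- stations[[k]]
    rel <- sweep(pos, 2, st$position)
    local <- quat_rotate(quat_conj(st$orientation), rel)
    visible <- local[, 2] > 0 & !occluded      # +y is the optical axis
    az <- atan2(local[, 1], local[, 2])
    el <- atan2(local[, 3], sqrt(local[, 1]^2 + local[, 2]^2))
    period <- st$sweep_period_s
    # %% can return the modulus itself for tiny negative angles; fold back
    clamp_period <- function(off) ifelse(off >= period, 0, off)
    az_off <- clamp_period((az %% (2 * pi)) / (2 * pi) * period)
    el_off <- clamp_period((el %% (2 * pi)) / (2 * pi) * period)
    if (timing_jitter_s > 0) {
      az_off <- clamp_period((az_off + rnorm(n, 0, timing_jitter_s)) %% period)
      el_off <- clamp_period((el_off + rnorm(n, 0, timing_jitter_s)) %% period)
    }
    out[[k]] <- data.frame(time_s = trajectory$time_s[visible],
                           sample = which(visible),
                           station_id = st$station_id,
                           az_offset_s = az_off[visible],
                           el_offset_s = el_off[visible])
    vis <- rbind(vis, data.frame(station_id = st$station_id,
                                 emitted = sum(visible),
                                 omitted = sum(!visible)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$sample, res$station_id), ]
  rownames(res) <- NULL
  attr(res, "visibility") <- vis
  res
}
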