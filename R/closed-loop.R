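#' Closed-loop harness configuration
#'
#' Parameters of the simulated-time loop: threshold detection on one ephys
#' channel, a host processing delay, and the downstream (device to host)
#' and upstream (command back to the headstage) link legs. The upstream
#' leg conventionally uses a block of one command frame, mirroring a
#' low-bandwidth control back-channel.
#'
#' @param detect_channel Channel index to monitor (1-based).
#' @param threshold_counts Detection threshold in ADC counts; its sign
#'   selects polarity (nonzero).
#' @param refractory_s Re-trigger suppression window, seconds (>= 0).
#' @param processing_delay_s Host computation time per event, seconds
#'   (>= 0).
#' @param link Downstream [link_config()].
#' @param uplink Upstream [link_config()]; default mirrors the downstream
#'   bandwidth/overhead with a one-command-frame block.
#' @param command_payload_bytes Payload size of a stimulation command frame
#'   (default 16: onset tick, pulse width, amplitude).
#' @return A `loop_config` object.
#' @export
loop_config <- function(detect_channel = 1L, threshold_counts = -200L,
                        refractory_s = 1e-3, processing_delay_s = 0,
                        link = link_config(),
                        uplink = NULL, command_payload_bytes = 16L) {
  stopifnot(refractory_s >= 0, processing_delay_s >= 0)
  if (threshold_counts == 0) stop("threshold_counts must be nonzero")
  cmd_frame <- FRAME_HEADER_BYTES + command_payload_bytes
  if (is.null(uplink)) {
    uplink <- link_config(link$link_bandwidth_bytes_per_s, cmd_frame,
                          link$per_transfer_overhead_s)
  }
  structure(list(detect_channel = as.integer(detect_channel),
                 threshold_counts = threshold_counts,
                 refractory_s = refractory_s,
                 processing_delay_s = processing_delay_s,
                 link = link, uplink = uplink,
                 command_payload_bytes = as.integer(command_payload_bytes)),
            class = "loop_config")
}

#' Threshold-crossing detection on an ephys stream
#'
#' Emits the first sample tick of each excursion beyond the threshold
#' (negative threshold: first sample at or below it; positive: at or
#' above), suppressing re-triggers within the refractory window.
#'
#' @param counts Integer matrix, samples x channels (as produced by
#'   [generate_ephys_frames()] / [ephys_counts()]).
#' @param channel Channel index.
#' @param threshold Threshold in counts (nonzero; sign selects polarity).
#' @param refractory_s Refractory window in seconds.
#' @param sample_rate_hz Sample rate of the stream.
#' @return Numeric vector of detection ticks (0-based sample indices).
#' @export
detect_crossings <- function(counts, channel, threshold, refractory_s = 0,
                             sample_rate_hz = 30000) {
  if (nrow(counts) == 0L) return(numeric(0))
  if (channel > ncol(counts)) stop("channel exceeds channel count")
  if (threshold == 0) stop("threshold must be nonzero")
  x <- counts[, channel]
  beyond <- if (threshold < 0) x <= threshold else x >= threshold
  onset <- beyond & !c(FALSE, beyond[-length(beyond)])
  ticks <- which(onset) - 1
  if (length(ticks) == 0L || refractory_s <= 0) return(as.double(ticks))
  refr <- refractory_s * sample_rate_hz
  keep <- numeric(length(ticks)); k <- 0L; last <- -Inf
  for (tk in ticks) {
    if (tk - last >= refr) { k <- k + 1L; keep[k] <- tk; last <- tk }
  }
  keep[seq_len(k)]
}

#' Nearest-rank percentile
#'
#' The worst-case style summary used for loop latencies: the smallest
#' element at rank `ceiling(p * n)` of the sorted sample.
#'
#' @param x Numeric vector.
#' @param p Probability in (0, 1].
#' @return The nearest-rank percentile.
#' @export
percentile_nearest_rank <- function(x, p) {
  stopifnot(length(x) > 0, p > 0, p <= 1)
  sort(x)[ceiling(p * length(x))]
}

#' Run the simulated closed loop
#'
#' Generates an ephys stream, detects threshold crossings, and accounts
#' end-to-end simulated-time latency for each event:
#' `(block delivery - event time) + processing delay + upstream command
#' transit`. The downstream term comes from [transfer_schedule()]; the
#' upstream term is one command frame through the uplink
#' (`block / bandwidth + overhead`). Detections whose block never delivers
#' (unflushed tail) are dropped and counted.
#'
#' @param ephys_config An [ephys_sim_config()].
#' @param config A [loop_config()].
#' @param duration_s Simulated duration in seconds.
#' @param spike_times Optional explicit spike times forwarded to
#'   [generate_ephys_frames()] (otherwise Poisson per the ephys config).
#' @return List: `latency_s` (per-event vector), `components` (data frame
#'   `tick`, `downstream_s`, `processing_s`, `upstream_s`, `total_s`),
#'   `summary` (list `n_events`, `median_s`, `p999_s`; all `NA` with
#'   `n_events = 0` when nothing was detected), `n_undelivered`.
#' @export
run_loop <- function(ephys_config, config, duration_s, spike_times = NULL) {
  sim <- generate_ephys_frames(ephys_config, duration_s, spike_times)
  fs <- ephys_config$sample_rate_hz
  map <- device_map(list(device_descriptor(
    1L, "ephys_source", "read",
    sample_payload_bytes = 2L * ephys_config$n_channels,
    nominal_rate_hz = fs)), clock_hz = fs)
  sched <- transfer_schedule(sim$frames, config$link, map)
  ticks <- detect_crossings(sim$counts, config$detect_channel,
                            config$threshold_counts, config$refractory_s,
                            fs)
  if (length(ticks) == 0L) {
    return(list(latency_s = numeric(0),
                components = data.frame(tick = numeric(0),
                                        downstream_s = numeric(0),
                                        processing_s = numeric(0),
                                        upstream_s = numeric(0),
                                        total_s = numeric(0)),
                summary = list(n_events = 0L, median_s = NA_real_,
                               p999_s = NA_real_),
                n_undelivered = 0L))
  }
  delivered <- sched$delivered_s[ticks + 1]   # frame row = tick + 1
  event_time <- ticks / fs
  down <- delivered - event_time
  keep <- !is.na(down)
  n_undelivered <- sum(!keep)
  up <- config$uplink$block_size_bytes /
    config$uplink$link_bandwidth_bytes_per_s +
    config$uplink$per_transfer_overhead_s
  comp <- data.frame(tick = ticks[keep],
                     downstream_s = down[keep],
                     processing_s = config$processing_delay_s,
                     upstream_s = up)
  comp$total_s <- comp$downstream_s + comp$processing_s + comp$upstream_s
  lat <- comp$total_s
  summary <- if (length(lat)) {
    list(n_events = length(lat), median_s = stats::median(lat),
         p999_s = percentile_nearest_rank(lat, 0.999))
  } else {
    list(n_events = 0L, median_s = NA_real_, p999_s = NA_real_)
  }
  list(latency_s = lat, components = comp, summary = summary,
       n_undelivered = n_undelivered)
}
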