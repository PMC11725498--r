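#' Block-transfer link configuration
#'
#' Host reads from the acquisition hardware happen in fixed-size blocks,
#' each transfer paying a small fixed overhead (system call, DMA setup).
#' The block size is settable: large blocks amortize overhead and raise
#' effective bandwidth, small blocks shorten the wait before data reach the
#' host. This object holds the three constants that govern the trade-off.
#'
#' @param link_bandwidth_bytes_per_s Physical ceiling of the serialized link
#'   in bytes per second (> 0).
#' @param block_size_bytes Read-block size in bytes (integer >= 1).
#' @param per_transfer_overhead_s Fixed cost per block transfer in seconds
#'   (>= 0).
#' @return A `link_config` object.
#' @export
link_config <- function(link_bandwidth_bytes_per_s = 150e6,
                        block_size_bytes = 8192L,
                        per_transfer_overhead_s = 0) {
  if (link_bandwidth_bytes_per_s <= 0) stop("link bandwidth must be > 0")
  if (block_size_bytes < 1 || block_size_bytes != trunc(block_size_bytes)) {
    stop("block_size_bytes must be an integer >= 1")
  }
  if (per_transfer_overhead_s < 0) stop("overhead must be >= 0")
  structure(list(link_bandwidth_bytes_per_s = as.double(link_bandwidth_bytes_per_s),
                 block_size_bytes = as.double(block_size_bytes),
                 per_transfer_overhead_s = as.double(per_transfer_overhead_s)),
            class = "link_config")
}

#' Block-fill latency in sample periods
#'
#' The number of sample periods that elapse before a read block fills,
#' which is the worst-case wait for the oldest sample in the block. With an
#' 8,192-byte block, a device producing 8 bytes per sample period waits
#' 1,024 periods; four probes producing 480 bytes each (1,920 B aggregate)
#' wait under five.
#'
#' @param block_size_bytes Block size in bytes (>= 1).
#' @param aggregate_sample_bytes Total encoded payload produced per sample
#'   period by all devices under assessment (>= 1).
#' @return Latency in sample periods (`block / aggregate`), a nonnegative
#'   real; convert to seconds by dividing by the sample rate.
#' @export
block_latency_samples <- function(block_size_bytes, aggregate_sample_bytes) {
  if (any(block_size_bytes < 1) || any(aggregate_sample_bytes < 1)) {
    stop_tethersim("domain", "arguments must be >= 1")
  }
  block_size_bytes / aggregate_sample_bytes
}

#' Effective bandwidth under per-transfer overhead
#'
#' Each block of `B` bytes takes `B / bandwidth + overhead` seconds, so the
#' achieved rate is `B / (B / bandwidth + overhead)`: monotonically
#' non-decreasing in block size and asymptoting to the link bandwidth.
#'
#' @param config A [link_config()].
#' @return Effective bandwidth in bytes per second.
#' @export
effective_bandwidth <- function(config) {
  b <- config$block_size_bytes
  b / (b / config$link_bandwidth_bytes_per_s + config$per_transfer_overhead_s)
}

#' Channel capacity of a link
#'
#' How many channels of fixed-rate, fixed-width data a given bandwidth
#' sustains: `floor(bandwidth / (rate * bytes))`. A 150 MB/s link carries
#' 2,500 channels of 30 kHz, 2-byte spike-band data.
#'
#' @param bandwidth_bytes_per_s Link bandwidth (> 0).
#' @param sample_rate_hz Per-channel sample rate (> 0).
#' @param bytes_per_sample Bytes per sample per channel (> 0).
#' @return Nonnegative integer channel count.
#' @export
channel_capacity <- function(bandwidth_bytes_per_s, sample_rate_hz,
                             bytes_per_sample) {
  if (bandwidth_bytes_per_s <= 0 || sample_rate_hz <= 0 ||
      bytes_per_sample <= 0) {
    stop_tethersim("domain", "all arguments must be positive")
  }
  floor(bandwidth_bytes_per_s / (sample_rate_hz * bytes_per_sample))
}

#' Simulated-time block transfer schedule
#'
#' Models the host reading the serialized byte stream in fixed-size blocks.
#' Encoded frames fill a byte FIFO; block `b` spans bytes
#' `((b-1)*B, b*B]` of the stream and fills when cumulative production
#' reaches `b * B` bytes. A frame is delivered when the block holding its
#' last byte is delivered, at (time that block filled)
#' `+ block_size / bandwidth + per_transfer_overhead`. A frame timestamped
#' at tick `k` is treated as produced at `(k + 1) / clock_hz` — the end of
#' its conversion period — so the oldest sample in a block waits the full
#' block-fill latency. The trailing underfull block is delivered only if
#' `flush_timeout_s` is finite (at last production + timeout + transit);
#' otherwise its frames get `NA` delivery times (flushing disabled, the
#' default). A single encoded frame larger than the block size is an error.
#'
#' @param frames A time-ordered [frame_stream()].
#' @param config A [link_config()].
#' @param map The governing [device_map()] (supplies `clock_hz`).
#' @param flush_timeout_s Optional flush timeout in seconds; default `Inf`
#'   (flushing disabled).
#' @return A data frame with one row per frame: `frame`, `block`,
#'   `produced_s`, `delivered_s` (NA for an unflushed tail).
#' @export
transfer_schedule <- function(frames, config, map, flush_timeout_s = Inf) {
  n <- n_frames(frames)
  if (n == 0L) {
    return(data.frame(frame = integer(0), block = integer(0),
                      produced_s = numeric(0), delivered_s = numeric(0)))
  }
  if (is.unsorted(frames$timestamp_ticks)) {
    stop("frames must be time-ordered; multiplex() first")
  }
  sizes <- FRAME_HEADER_BYTES + lengths(frames$payloads)
  B <- config$block_size_bytes
  if (any(sizes > B)) {
    stop_tethersim("block_overflow",
                   "an encoded frame exceeds the block size")
  }
  ends <- cumsum(as.double(sizes))            # offset of each frame's last byte
  block <- ceiling(ends / B)                  # block holding that byte
  produced <- (frames$timestamp_ticks + 1) / map$clock_hz
  transit <- B / config$link_bandwidth_bytes_per_s +
    config$per_transfer_overhead_s
  n_blocks <- block[n]
  bb <- seq_len(n_blocks)
  # frame whose bytes complete block b: first i with ends[i] >= b * B
  filler <- findInterval(bb * B - 0.5, ends) + 1L
  delivered_block <- numeric(n_blocks)
  full <- filler <= n                          # blocks that actually fill
  delivered_block[full] <- produced[filler[full]] + transit
  if (any(!full)) {                            # trailing partial block
    delivered_block[!full] <- if (is.finite(flush_timeout_s)) {
      produced[n] + flush_timeout_s + transit
    } else NA_real_
  }
  data.frame(frame = seq_len(n), block = as.integer(block),
             produced_s = produced,
             delivered_s = delivered_block[block])
}
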