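# Shared fixtures and independent oracles.

# small heterogeneous map: device 1 fixed 4-byte, devices 2/3 variable
tiny_map <- function(clock_hz = 30000) {
  device_map(list(
    device_descriptor(1L, "ephys_source", "read", sample_payload_bytes = 4L,
                      nominal_rate_hz = clock_hz),
    device_descriptor(2L, "orientation_source", "read"),
    device_descriptor(3L, "generic", "read_write")),
    clock_hz = clock_hz)
}

# random variable-length frames on device 2/3, sorted timestamps
random_stream <- function(n, seed, max_payload = 64L) {
  set.seed(seed)
  frame_stream(
    device_id = sample(c(2, 3), n, replace = TRUE),
    timestamp_ticks = sort(floor(runif(n, 0, 2^48))),
    payloads = lapply(sample(0:max_payload, n, replace = TRUE),
                      function(k) as.raw(sample(0:255, k, replace = TRUE))))
}

# brute-force byte-splitter oracle: recompute each frame's byte offsets
# from known sizes and slice the encoded blob directly
oracle_split <- function(bytes, sizes) {
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  lapply(seq_along(sizes), function(i) bytes[starts[i]:ends[i]])
}

# brute-force byte-FIFO transfer model, written independently of
# transfer_schedule(): walk bytes one frame at a time, track block fills
oracle_schedule <- function(sizes, produced_s, block, bw, overhead) {
  n <- length(sizes)
  delivered <- rep(NA_real_, n)
  cum <- 0
  fills <- list()  # block index -> fill time
  for (i in seq_len(n)) cum <- cum + sizes[i]
  total_blocks <- ceiling(cum / block)
  cum <- 0
  fill_time <- rep(NA_real_, total_blocks)
  for (i in seq_len(n)) {
    before <- cum
    cum <- cum + sizes[i]
    b_lo <- floor(before / block) + 1
    b_hi <- ceiling(cum / block)
    for (b in b_lo:b_hi) {
      if (cum >= b * block && is.na(fill_time[b])) {
        fill_time[b] <- produced_s[i]
      }
    }
  }
  for (i in seq_len(n)) {
    b <- ceiling(cumsum(sizes)[i] / block)
    if (!is.na(fill_time[b])) {
      delivered[i] <- fill_time[b] + block / bw + overhead
    }
  }
  delivered
}

# tolerance-checked expectation for numeric vectors
expect_near <- function(object, expected, tol = 1e-9) {
  expect_true(max(abs(object - expected)) <= tol)
}
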