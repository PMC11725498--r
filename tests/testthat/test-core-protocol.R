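test_that("encode_frame emits the documented little-endian layout", {
  map <- tiny_map()
  # empty payload: 14 bytes, last two (length field) zero
  enc0 <- encode_frame(list(device_id = 2, timestamp_ticks = 0,
                            payload = raw(0)), map)
  expect_length(enc0, 14)
  expect_identical(enc0[13:14], as.raw(c(0, 0)))
  # hand-computed layout: id 3 (4 B LE), t = 256 (8 B LE), len 2, payload
  enc <- encode_frame(list(device_id = 3, timestamp_ticks = 256,
                           payload = as.raw(c(0xAA, 0xBB))), map)
  expect_identical(enc, as.raw(c(0x03, 0, 0, 0,
                                 0x00, 0x01, 0, 0, 0, 0, 0, 0,
                                 0x02, 0x00, 0xAA, 0xBB)))
})

test_that("codec roundtrips arbitrary frames and reports bytes consumed", {
  map <- tiny_map()
  set.seed(42)
  for (i in 1:200) {
    f <- list(device_id = sample(c(2, 3), 1),
              timestamp_ticks = floor(runif(1, 0, 2^50)),
              payload = as.raw(sample(0:255, sample(0:80, 1),
                                      replace = TRUE)))
    enc <- encode_frame(f, map)
    dec <- decode_frame(enc, map)
    expect_identical(dec$frame$payload, f$payload)
    expect_identical(dec$frame$device_id, f$device_id)
    expect_identical(dec$frame$timestamp_ticks, f$timestamp_ticks)
    expect_identical(dec$consumed, 14 + length(f$payload))
  }
})

test_that("codec errors: unknown device, size mismatch, overflow, truncation", {
  map <- tiny_map()
  expect_error(encode_frame(list(device_id = 9, timestamp_ticks = 0,
                                 payload = raw(0)), map),
               class = "tethersim_unknown_device")
  # device 1 is fixed at 4 bytes
  expect_error(encode_frame(list(device_id = 1, timestamp_ticks = 0,
                                 payload = raw(3)), map),
               class = "tethersim_payload_size")
  expect_error(encode_frame(list(device_id = 2, timestamp_ticks = 0,
                                 payload = raw(65536)), map),
               class = "tethersim_payload_overflow")
  expect_error(decode_frame(raw(13), map),
               class = "tethersim_incomplete_frame")
  enc <- encode_frame(list(device_id = 2, timestamp_ticks = 1,
                           payload = as.raw(1:5)), map)
  expect_error(decode_frame(enc[1:16], map),
               class = "tethersim_incomplete_frame")
  expect_error(decode_frame(encode_frame(
    list(device_id = 7, timestamp_ticks = 0, payload = raw(0)),
    device_map(list(device_descriptor(7L)))), map),
    class = "tethersim_unknown_device")
})

test_that("stream encode/decode matches a brute-force byte splitter", {
  map <- tiny_map()
  s <- random_stream(50, seed = 7)
  blob <- encode_stream(s, map)
  sizes <- 14 + lengths(s$payloads)
  expect_equal(length(blob), sum(sizes))
  # oracle: slice the blob at offsets recomputed from the known sizes and
  # check every piece equals a per-frame encode
  pieces <- oracle_split(blob, sizes)
  for (i in seq_along(pieces)) {
    expect_identical(pieces[[i]], encode_frame(stream_frame(s, i), map))
  }
  dec <- decode_stream(blob, map)
  expect_identical(dec$device_id, s$device_id)
  expect_identical(dec$timestamp_ticks, s$timestamp_ticks)
  expect_identical(dec$payloads, s$payloads)
  expect_identical(attr(dec, "bytes_consumed"), sum(sizes))
})

test_that("multiplex sorts by time, breaks ties by device then arrival", {
  map <- tiny_map()
  a <- frame_stream(c(2, 2, 2), c(0, 5, 10),
                    list(as.raw(1), as.raw(2), as.raw(3)))
  # identity on a single stream
  m1 <- multiplex(list(a), map)
  expect_identical(m1$timestamp_ticks, a$timestamp_ticks)
  expect_identical(m1$payloads, a$payloads)
  # interleaved merge equals concatenate-then-stable-sort oracle
  b <- frame_stream(c(3, 3), c(3, 7), list(as.raw(9), as.raw(8)))
  m <- multiplex(list(a, b), map)
  ids <- c(a$device_id, b$device_id)
  ts <- c(a$timestamp_ticks, b$timestamp_ticks)
  ord <- order(ts, ids)              # base-R stable sort oracle
  expect_identical(m$timestamp_ticks, ts[ord])
  expect_identical(m$device_id, ids[ord])
  # equal timestamps: device 1 before device 2
  x2 <- frame_stream(2, 100, list(as.raw(2)))
  x1 <- frame_stream(1, 100, list(as.raw(c(1, 1, 1, 1))))
  tie <- multiplex(list(x2, x1), map)
  expect_identical(tie$device_id, c(1, 2))
  # multiset conservation and per-device order preservation (property)
  set.seed(11)
  for (k in 1:10) {
    s1 <- random_stream(20, seed = k)
    s2 <- random_stream(15, seed = 100 + k)
    mm <- multiplex(list(s1, s2), map)
    expect_identical(n_frames(mm), 35L)
    expect_false(is.unsorted(mm$timestamp_ticks))
    expect_setequal(sapply(mm$payloads, paste, collapse = ","),
                    c(sapply(s1$payloads, paste, collapse = ","),
                      sapply(s2$payloads, paste, collapse = ",")))
  }
})

test_that("device map JSON roundtrips and enforces invariants", {
  expect_error(device_map(list(device_descriptor(1), device_descriptor(1))),
               "duplicate")
  expect_error(device_map(list(device_descriptor(1)), clock_hz = 0),
               "clock_hz")
  expect_error(device_descriptor(1, sample_payload_bytes = -1))
  map <- tiny_map()
  path <- tempfile(fileext = ".json")
  write_device_map(map, path)
  rt <- read_device_map(path)
  expect_equal(rt$clock_hz, map$clock_hz)
  expect_equal(lapply(rt$devices, unclass), lapply(map$devices, unclass))
})
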