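#' Device descriptors and device maps
#'
#' A device map is the registry of heterogeneous sources and sinks sharing a
#' single serialized link: amplifiers, orientation sensors, optical-tracking
#' receivers, stimulators and the like. Every frame on the link names one of
#' its devices, and all devices share one acquisition clock.
#'
#' @param device_id Unsigned integer, unique within a map.
#' @param kind One of `"ephys_source"`, `"orientation_source"`,
#'   `"lighthouse_source"`, `"heartbeat_source"`, `"stimulator_sink"`,
#'   `"led_sink"`, `"generic"`.
#' @param direction One of `"read"`, `"write"`, `"read_write"`.
#' @param sample_payload_bytes Fixed payload size per frame in bytes for
#'   fixed-rate devices; 0 marks a variable-length device.
#' @param nominal_rate_hz Nominal sample rate; 0 for event-driven devices.
#' @param description Free text.
#' @return A `device_descriptor` object.
#' @export
device_descriptor <- function(device_id, kind = "generic", direction = "read",
                              sample_payload_bytes = 0L, nominal_rate_hz = 0,
                              description = "") {
  kinds <- c("ephys_source", "orientation_source", "lighthouse_source",
             "heartbeat_source", "stimulator_sink", "led_sink", "generic")
  kind <- match.arg(kind, kinds)
  direction <- match.arg(direction, c("read", "write", "read_write"))
  if (length(device_id) != 1L || is.na(device_id) || device_id < 0 ||
      device_id != trunc(device_id)) {
    stop("device_id must be a single nonnegative integer")
  }
  if (sample_payload_bytes < 0) stop("sample_payload_bytes must be >= 0")
  if (nominal_rate_hz < 0) stop("nominal_rate_hz must be >= 0")
  structure(
    list(device_id = as.double(device_id), kind = kind, direction = direction,
         sample_payload_bytes = as.double(sample_payload_bytes),
         nominal_rate_hz = as.double(nominal_rate_hz),
         description = as.character(description)),
    class = "device_descriptor")
}

#' @param devices List of [device_descriptor()] objects.
#' @param clock_hz Frequency of the shared acquisition tick counter (Hz).
#'   Default 30000 so that one tick equals one spike-band sample period.
#' @rdname device_descriptor
#' @export
device_map <- function(devices, clock_hz = 30000) {
  if (inherits(devices, "device_descriptor")) devices <- list(devices)
  stopifnot(is.list(devices))
  for (d in devices) {
    if (!inherits(d, "device_descriptor")) {
      stop("devices must all be device_descriptor objects")
    }
  }
  ids <- vapply(devices, `[[`, numeric(1), "device_id")
  if (anyDuplicated(ids)) stop("duplicate device_id in device map")
  if (length(clock_hz) != 1L || is.na(clock_hz) || clock_hz <= 0) {
    stop("clock_hz must be a single positive number")
  }
  structure(list(devices = devices, clock_hz = as.double(clock_hz)),
            class = "device_map")
}

#' @export
print.device_map <- function(x, ...) {
  cat(sprintf("<device_map: %d device(s), clock %g Hz>\n",
              length(x$devices), x$clock_hz))
  for (d in x$devices) {
    cat(sprintf("  [%d] %s (%s, %d B/frame, %g Hz) %s\n",
                d$device_id, d$kind, d$direction, d$sample_payload_bytes,
                d$nominal_rate_hz, d$description))
  }
  invisible(x)
}

map_lookup <- function(map, device_id) {
  for (d in map$devices) if (d$device_id == device_id) return(d)
  stop_tethersim("unknown_device",
                 sprintf("device_id %s not present in device map", device_id))
}

stop_tethersim <- function(class, message) {
  stop(structure(class = c(paste0("tethersim_", class), "error", "condition"),
                 list(message = message, call = sys.call(-1))))
}

#' Frame streams
#'
#' A frame is the atomic acquisition unit: a device id, a timestamp on the
#' shared clock (in ticks), and a payload of bytes. `frame_stream()` holds
#' frames in columnar form (id vector, tick vector, payload list) so large
#' streams can be manipulated without per-frame object overhead.
#'
#' @param device_id Integer vector of device ids.
#' @param timestamp_ticks Numeric vector of shared-clock tick counts
#'   (nonnegative, exact up to 2^53).
#' @param payloads List of raw vectors, one per frame.
#' @return A `frame_stream` object.
#' @export
frame_stream <- function(device_id = numeric(0), timestamp_ticks = numeric(0),
                         payloads = list()) {
  n <- length(device_id)
  stopifnot(length(timestamp_ticks) == n, length(payloads) == n)
  if (n && (any(device_id < 0) || any(timestamp_ticks < 0))) {
    stop("device ids and timestamps must be nonnegative")
  }
  structure(list(device_id = as.double(device_id),
                 timestamp_ticks = as.double(timestamp_ticks),
                 payloads = payloads),
            class = "frame_stream")
}

#' @rdname frame_stream
#' @param x A `frame_stream`.
#' @export
n_frames <- function(x) length(x$device_id)

#' @export
print.frame_stream <- function(x, ...) {
  cat(sprintf("<frame_stream: %d frame(s), %d device id(s), %s payload bytes>\n",
              n_frames(x), length(unique(x$device_id)),
              format(sum(lengths(x$payloads)), big.mark = ",")))
  invisible(x)
}

#' @rdname frame_stream
#' @param i Frame index.
#' @export
stream_frame <- function(x, i) {
  list(device_id = x$device_id[i], timestamp_ticks = x$timestamp_ticks[i],
       payload = x$payloads[[i]])
}

validate_frame <- function(device_id, payload, map) {
  d <- map_lookup(map, device_id)
  if (length(payload) > 65535) {
    stop_tethersim("payload_overflow",
                   "payload exceeds 65,535 bytes; chunk at the producer")
  }
  if (d$sample_payload_bytes > 0 &&
      length(payload) != d$sample_payload_bytes) {
    stop_tethersim("payload_size", sprintf(
      "device %d is fixed-size (%d B) but payload has %d B",
      d$device_id, d$sample_payload_bytes, length(payload)))
  }
  invisible(TRUE)
}

FRAME_HEADER_BYTES <- 14L

#' Encode and decode frames
#'
#' The wire layout multiplexing all devices onto one ordered byte channel is
#' a 14-byte little-endian header — device id (4 B unsigned), timestamp
#' (8 B unsigned), payload length (2 B unsigned) — followed by the payload.
#'
#' @param frame A list with `device_id`, `timestamp_ticks`, `payload` (raw),
#'   e.g. from [stream_frame()].
#' @param map The governing [device_map()].
#' @return `encode_frame()`: a raw vector of length `14 + payload length`.
#' @export
encode_frame <- function(frame, map) {
  validate_frame(frame$device_id, frame$payload, map)
  c(uint_to_raw(frame$device_id, 4L),
    uint_to_raw(frame$timestamp_ticks, 8L),
    uint_to_raw(length(frame$payload), 2L),
    frame$payload)
}

#' @param bytes Raw vector starting at a frame boundary.
#' @return `decode_frame()`: a list with `frame` and `consumed` (byte count),
#'   so byte streams can be parsed incrementally.
#' @rdname encode_frame
#' @export
decode_frame <- function(bytes, map) {
  if (length(bytes) < FRAME_HEADER_BYTES) {
    stop_tethersim("incomplete_frame", "fewer than 14 header bytes available")
  }
  device_id <- raw_to_uint(bytes[1:4])
  ts <- raw_to_uint(bytes[5:12])
  len <- raw_to_uint(bytes[13:14])
  total <- FRAME_HEADER_BYTES + len
  if (length(bytes) < total) {
    stop_tethersim("incomplete_frame",
                   sprintf("need %d bytes for payload, have %d",
                           total, length(bytes)))
  }
  payload <- if (len > 0) bytes[(FRAME_HEADER_BYTES + 1):total] else raw(0)
  validate_frame(device_id, payload, map)
  list(frame = list(device_id = device_id, timestamp_ticks = ts,
                    payload = payload),
       consumed = total)
}

#' Encode or decode a whole stream
#'
#' @param stream A [frame_stream()].
#' @inheritParams encode_frame
#' @return `encode_stream()`: one raw vector, the concatenation of all
#'   encoded frames (length is exactly `sum(14 + payload lengths)`).
#' @export
encode_stream <- function(stream, map) {
  n <- n_frames(stream)
  if (n == 0L) return(raw(0))
  for (i in seq_len(n)) {
    validate_frame(stream$device_id[i], stream$payloads[[i]], map)
  }
  lens <- lengths(stream$payloads)
  headers <- rbind(matrix(uints_to_raw_vec(stream$device_id, 4L), nrow = 4L),
                   matrix(uints_to_raw_vec(stream$timestamp_ticks, 8L), nrow = 8L),
                   matrix(uints_to_raw_vec(lens, 2L), nrow = 2L))
  pieces <- vector("list", 2L * n)
  pieces[seq(1L, by = 2L, length.out = n)] <-
    lapply(seq_len(n), function(i) headers[, i])
  pieces[seq(2L, by = 2L, length.out = n)] <- stream$payloads
  unlist(pieces, use.names = FALSE)
}

#' @param bytes Raw vector of concatenated encoded frames.
#' @param allow_partial If `TRUE`, a truncated final frame produces a warning
#'   and the complete frames are returned; if `FALSE` it is an error.
#' @return `decode_stream()`: a [frame_stream()]; attribute `bytes_consumed`
#'   reports how much input was parsed.
#' @rdname encode_stream
#' @export
decode_stream <- function(bytes, map, allow_partial = FALSE) {
  ids <- numeric(0); ts <- numeric(0); pl <- list()
  offset <- 0L
  n_total <- length(bytes)
  while (offset < n_total) {
    res <- tryCatch(
      decode_frame(bytes[(offset + 1L):n_total], map),
      tethersim_incomplete_frame = function(e) e)
    if (inherits(res, "tethersim_incomplete_frame")) {
      if (allow_partial) {
        warning(sprintf("truncated tail: %d trailing byte(s) ignored",
                        n_total - offset))
        break
      }
      stop(res)
    }
    ids <- c(ids, res$frame$device_id)
    ts <- c(ts, res$frame$timestamp_ticks)
    pl[[length(pl) + 1L]] <- res$frame$payload
    offset <- offset + res$consumed
  }
  out <- frame_stream(ids, ts, pl)
  attr(out, "bytes_consumed") <- offset
  out
}

#' Multiplex per-device streams into one ordered stream
#'
#' Merges individually time-ordered per-device frame sequences into the
#' single ordered channel the link carries. Ordering is by timestamp, ties
#' broken by ascending device id, then by per-device arrival order; the
#' merge is stable with respect to each input stream and conserves frames.
#'
#' @param streams A list of [frame_stream()] objects, each time-ordered.
#' @param map The governing [device_map()] (frames are validated against it).
#' @return One [frame_stream()].
#' @export
multiplex <- function(streams, map) {
  if (inherits(streams, "frame_stream")) streams <- list(streams)
  ids <- unlist(lapply(streams, `[[`, "device_id"), use.names = FALSE)
  if (is.null(ids)) ids <- numeric(0)
  ts <- unlist(lapply(streams, `[[`, "timestamp_ticks"), use.names = FALSE)
  if (is.null(ts)) ts <- numeric(0)
  pl <- do.call(c, c(lapply(streams, `[[`, "payloads"), list(list())))
  for (s in streams) {
    if (n_frames(s) && is.unsorted(s$timestamp_ticks)) {
      stop("each per-device input stream must be time-ordered")
    }
  }
  arrival <- unlist(lapply(streams, function(s) seq_len(n_frames(s))),
                    use.names = FALSE)
  if (is.null(arrival)) arrival <- integer(0)
  ord <- order(ts, ids, arrival, method = "radix")
  for (id in unique(ids)) map_lookup(map, id)
  frame_stream(ids[ord], ts[ord], pl[ord])
}

#' Read or write a device map as JSON
#'
#' @param map A [device_map()].
#' @param path File path.
#' @export
write_device_map <- function(map, path) {
  devs <- lapply(map$devices, function(d) d[c(
    "device_id", "kind", "direction", "sample_payload_bytes",
    "nominal_rate_hz", "description")])
  jsonlite::write_json(list(clock_hz = map$clock_hz, devices = devs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_device_map
#' @export
read_device_map <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$clock_hz) || is.null(x$devices)) {
    stop_tethersim("format", "device map JSON must have clock_hz and devices")
  }
  devs <- lapply(x$devices, function(d) {
    device_descriptor(d$device_id, d$kind, d$direction,
                      d$sample_payload_bytes, d$nominal_rate_hz,
                      if (is.null(d$description)) "" else d$description)
  })
  device_map(devs, clock_hz = x$clock_hz)
}
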