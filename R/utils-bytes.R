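# Little-endian integer <-> raw helpers.
#
# R has no native unsigned 64-bit integer; tick counters are carried as
# doubles, which are exact up to 2^53 (~9.5 million years at 30 kHz).

uint_to_raw <- function(x, nbytes) {
  stopifnot(length(x) == 1L, !is.na(x), x >= 0)
  if (x >= 2^53) stop("tick value exceeds exact double range (2^53)")
  out <- raw(nbytes)
  for (i in seq_len(nbytes)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  if (x != 0) stop("value does not fit in ", nbytes, " bytes")
  out
}

raw_to_uint <- function(r) {
  sum(as.double(as.integer(r)) * 256^(seq_along(r) - 1))
}

# Vectorised encode of many uints into an nbytes-per-value raw vector,
# column-per-byte then interleaved.  Used by the stream encoder.
uints_to_raw_vec <- function(x, nbytes) {
  n <- length(x)
  if (n == 0L) return(raw(0))
  m <- matrix(0L, nrow = nbytes, ncol = n)
  xx <- as.double(x)
  for (i in seq_len(nbytes)) {
    m[i, ] <- as.integer(xx %% 256)
    xx <- xx %/% 256
  }
  as.raw(m)
}
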