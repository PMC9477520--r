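# Internal helpers: classed errors, big-endian integer packing, byte cursors.
# Values are carried as doubles (exact below 2^53), wide enough for every
# field this dialect writes.

kff_stop <- function(class, fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(structure(
    class = c(paste0("kff_", class, "_error"), "kff_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# bytes needed to represent the unsigned value v (true bit length)
width_bytes <- function(v) {
  w <- 1L
  while (v >= 256^w) w <- w + 1L
  w
}

int_to_be <- function(x, width) {
  if (x < 0 || x >= 256^width) {
    kff_stop("overflow", "value %.0f does not fit in %d byte(s)", x, width)
  }
  out <- integer(width)
  for (i in rev(seq_len(width))) {
    out[i] <- x %% 256
    x <- x %/% 256
  }
  as.raw(out)
}

be_to_int <- function(bytes) {
  x <- 0
  for (b in as.integer(bytes)) x <- x * 256 + b
  x
}

# signed 8-byte big-endian two's complement, byte-wise so no double rounding
sint_to_be8 <- function(x) {
  if (x >= 0) return(int_to_be(x, 8L))
  b <- 255L - as.integer(int_to_be(-x, 8L))
  carry <- 1L
  for (i in 8:1) {
    v <- b[i] + carry
    b[i] <- v %% 256L
    carry <- v %/% 256L
    if (!carry) break
  }
  as.raw(b)
}

be8_to_sint <- function(bytes) {
  b <- as.integer(bytes)
  if (b[1] < 128L) return(be_to_int(b))
  b <- 255L - b
  carry <- 1L
  for (i in 8:1) {
    v <- b[i] + carry
    b[i] <- v %% 256L
    carry <- v %/% 256L
    if (!carry) break
  }
  -be_to_int(b)
}

# sequential reader over a raw vector
new_cursor <- function(bytes) {
  cur <- new.env(parent = emptyenv())
  cur$bytes <- bytes
  cur$pos <- 1L
  cur
}

cursor_remaining <- function(cur) length(cur$bytes) - cur$pos + 1L

cursor_take <- function(cur, n, what = "data") {
  if (n == 0) return(raw(0))
  if (cursor_remaining(cur) < n) {
    kff_stop("truncation", "truncated stream: needed %d byte(s) for %s at offset %d",
             n, what, cur$pos - 1L)
  }
  out <- cur$bytes[cur$pos:(cur$pos + n - 1L)]
  cur$pos <- cur$pos + as.integer(n)
  out
}

# NUL-terminated ASCII string
cursor_take_cstring <- function(cur) {
  bytes <- cur$bytes
  i <- cur$pos
  while (i <= length(bytes) && bytes[i] != as.raw(0)) i <- i + 1L
  if (i > length(bytes)) kff_stop("truncation", "unterminated string at offset %d", cur$pos - 1L)
  out <- if (i == cur$pos) "" else rawToChar(bytes[cur$pos:(i - 1L)])
  cur$pos <- i + 1L
  out
}
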