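# Bit-exact serialization of the KFF dialect.
#
# Layout (all multi-byte integers big-endian):
#   header:  "KFF" | major | minor | encoding byte | unique | canonical
#            | 4-byte free_size | metadata bytes
#   V:  'v' | 8-byte var count | per var: NUL-terminated ASCII name + 8-byte value
#   R:  'r' | 4-byte block count | per block: n in w_n bytes (omitted when
#       max = 1) | packed sequence of n+k-1 nt | n*data_size data bytes
#   M:  'm' | packed minimizer (ceil(m/4) bytes) | 4-byte block count | per
#       block: n in w_n bytes | position in w_p bytes | packed skeleton of
#       n+k-1-m nt | n*data_size data bytes
#   I:  'i' | 4-byte entry count | per entry: type byte + signed 8-byte
#       offset relative to the first byte AFTER this section | signed 8-byte
#       offset to the next index section (0 = none)
#   footer: "KFF" end-magic (its absence is a validation warning, not a
#       fatal read error: streams may be truncated deliberately)
#
# Field widths are computed from the variable state alone: w_n is the byte
# length of max (field omitted when max = 1, n is then 1) and w_p the byte
# length of max + k - 1 - m, using the true bit length of the value so the
# largest legal position always fits.

KFF_MAGIC <- charToRaw("KFF")

wn_of <- function(maxn) if (maxn == 1) 0L else width_bytes(maxn)
wp_of <- function(maxn, k, m) width_bytes(max(1, maxn + k - 1 - m))

serialize_header <- function(header) {
  c(KFF_MAGIC,
    as.raw(c(header$version_major, header$version_minor)),
    encoding_to_byte(header$encoding),
    as.raw(as.integer(header$unique_kmers)),
    as.raw(as.integer(header$canonical_kmers)),
    int_to_be(length(header$metadata), 4L),
    header$metadata)
}

serialize_section_v <- function(section) {
  vars <- section$vars
  pieces <- lapply(names(vars), function(nm) {
    b <- charToRaw(nm)
    if (!length(b) || any(b > as.raw(127)) || any(b == as.raw(0))) {
      kff_stop("variable", "variable name '%s' must be non-empty ASCII", nm)
    }
    c(b, as.raw(0), int_to_be(vars[[nm]], 8L))
  })
  c(charToRaw("v"), int_to_be(length(vars), 8L), unlist(pieces))
}

check_block_n <- function(n, maxn, i, declared = NULL) {
  if (!is.null(declared) && declared != n) {
    kff_stop("block", "block %d: declared n=%d but sequence implies %d", i, declared, n)
  }
  if (n < 1) kff_stop("block", "block %d is empty (no k-mer window)", i)
  if (n > maxn) kff_stop("block", "block %d: n=%d exceeds max=%d", i, n, maxn)
  n
}

serialize_section_r <- function(section, state, enc) {
  state_require(state, c("k", "max", "data_size"), "ordering")
  k <- state_get(state, "k"); maxn <- state_get(state, "max")
  ds <- state_get(state, "data_size")
  w_n <- wn_of(maxn)
  blocks <- section$blocks
  head <- c(charToRaw("r"), int_to_be(length(blocks), 4L))

  if (maxn == 1 && length(blocks) > 64) {
    # vectorised path: every block is a single k-mer, no n field
    seqs <- vapply(blocks, function(b) b$sequence, character(1))
    if (any(nchar(seqs) != k)) {
      i <- which(nchar(seqs) != k)[1]
      check_block_n(nchar(seqs[i]) - k + 1, maxn, i, blocks[[i]]$n)
    }
    payload <- pack_equal_length(seqs, enc)
    if (ds == 0) return(c(head, payload))
    data <- unlist(lapply(blocks, function(b) b$data))
    if (length(data) != ds * length(blocks)) {
      kff_stop("block", "data payloads do not total n*data_size bytes")
    }
    bpk <- ceiling(k / 4)
    body <- rbind(matrix(payload, nrow = bpk), matrix(data, nrow = ds))
    return(c(head, as.raw(body)))
  }

  pieces <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    n <- check_block_n(nchar(b$sequence) - k + 1, maxn, i, b$n)
    if (length(b$data) != n * ds) {
      kff_stop("block", "block %d: data has %d byte(s), expected %d", i,
               length(b$data), n * ds)
    }
    pieces[[i]] <- c(if (w_n) int_to_be(n, w_n),
                     pack_codes(seq_to_codes(b$sequence, enc)),
                     b$data)
  }
  c(head, unlist(pieces))
}

serialize_section_m <- function(section, state, enc) {
  state_require(state, c("k", "max", "data_size"), "ordering")
  state_require(state, "m", "variable")
  k <- state_get(state, "k"); maxn <- state_get(state, "max")
  ds <- state_get(state, "data_size"); m <- state_get(state, "m")
  if (nchar(section$minimizer) != m) {
    kff_stop("block", "minimizer '%s' has length %d, expected m=%d",
             section$minimizer, nchar(section$minimizer), m)
  }
  w_n <- wn_of(maxn)
  w_p <- wp_of(maxn, k, m)
  pieces <- vector("list", length(section$blocks))
  for (i in seq_along(section$blocks)) {
    b <- section$blocks[[i]]
    n <- check_block_n(nchar(b$skeleton) - k + 1 + m, maxn, i, b$n)
    if (b$minimizer_position < 0 || b$minimizer_position > nchar(b$skeleton)) {
      kff_stop("block", "block %d: minimizer position %d out of range 0..%d",
               i, b$minimizer_position, nchar(b$skeleton))
    }
    if (length(b$data) != n * ds) {
      kff_stop("block", "block %d: data has %d byte(s), expected %d", i,
               length(b$data), n * ds)
    }
    pieces[[i]] <- c(if (w_n) int_to_be(n, w_n),
                     int_to_be(b$minimizer_position, w_p),
                     pack_codes(seq_to_codes(b$skeleton, enc)),
                     b$data)
  }
  c(charToRaw("m"),
    pack_codes(seq_to_codes(section$minimizer, enc)),
    int_to_be(length(section$blocks), 4L),
    unlist(pieces))
}

serialize_section_i <- function(section) {
  e <- section$entries
  pieces <- lapply(seq_len(nrow(e)), function(i) {
    c(charToRaw(e$section_type[i]), sint_to_be8(e$relative_offset[i]))
  })
  c(charToRaw("i"), int_to_be(nrow(e), 4L), unlist(pieces),
    sint_to_be8(section$next_index))
}

serialize_section <- function(section, state, enc) {
  out <- switch(section$type,
    v = serialize_section_v(section),
    r = serialize_section_r(section, state, enc),
    m = serialize_section_m(section, state, enc),
    i = serialize_section_i(section),
    kff_stop("section", "unknown section type '%s'", section$type)
  )
  if (section$type == "v") state_update(state, section$vars)
  out
}

#' Serialize a KFF file model to bytes
#'
#' @param file A [kff_file()]. Section order must satisfy the variable
#'   preconditions: a V section defining `k`, `max` and `data_size` precedes
#'   the first R/M section (`m` additionally before the first M section).
#' @return Raw vector of the complete file, with an attribute
#'   `section_offsets` (data.frame of `type`, `start`, `length`; 0-based
#'   absolute byte offsets).
#' @seealso [kff_write()], [kff_parse()]
#' @export
kff_serialize <- function(file) {
  stopifnot(inherits(file, "kff_file"))
  head <- serialize_header(file$header)
  state <- new_state()
  n <- length(file$sections)
  pieces <- vector("list", n)
  starts <- numeric(n)
  at <- length(head)
  for (i in seq_len(n)) {
    pieces[[i]] <- serialize_section(file$sections[[i]], state, file$header$encoding)
    starts[i] <- at
    at <- at + length(pieces[[i]])
  }
  bytes <- c(head, unlist(pieces), KFF_MAGIC)
  attr(bytes, "section_offsets") <- data.frame(
    type = vapply(file$sections, function(s) s$type, character(1)),
    start = starts,
    length = vapply(pieces, length, numeric(1)),
    stringsAsFactors = FALSE
  )
  bytes
}

#' Write a KFF file to disk
#'
#' @param file A [kff_file()].
#' @param path Output path.
#' @return Invisibly, the number of bytes written.
#' @export
kff_write <- function(file, path) {
  bytes <- kff_serialize(file)
  con <- base::file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(bytes), con)
  invisible(length(bytes))
}

# parsing --------------------------------------------------------------------

parse_header <- function(cur) {
  magic <- cursor_take(cur, 3L, "magic")
  if (!identical(magic, KFF_MAGIC)) {
    kff_stop("magic", "not a KFF stream (leading bytes %s)",
             paste(sprintf("%02x", as.integer(magic)), collapse = " "))
  }
  ver <- as.integer(cursor_take(cur, 2L, "version"))
  enc <- byte_to_encoding(cursor_take(cur, 1L, "encoding"))
  uniq <- as.integer(cursor_take(cur, 1L, "flags")) != 0L
  canon <- as.integer(cursor_take(cur, 1L, "flags")) != 0L
  free_size <- be_to_int(cursor_take(cur, 4L, "free_size"))
  metadata <- cursor_take(cur, free_size, "metadata")
  kff_header(enc, uniq, canon, metadata, version = ver)
}

parse_packed <- function(cur, nt, enc, what) {
  payload <- cursor_take(cur, ceiling(nt / 4), what)
  decode_sequence(payload, enc, length = nt)
}

parse_section_v <- function(cur) {
  count <- be_to_int(cursor_take(cur, 8L, "variable count"))
  nms <- character(count)
  vals <- numeric(count)
  for (i in seq_len(count)) {
    nm <- cursor_take_cstring(cur)
    if (!nzchar(nm) || any(charToRaw(nm) > as.raw(127))) {
      kff_stop("variable", "malformed variable name in V section")
    }
    nms[i] <- nm
    vals[i] <- be_to_int(cursor_take(cur, 8L, "variable value"))
  }
  names(vals) <- nms
  do.call(kff_section_v, as.list(vals))
}

parse_section_r <- function(cur, state, enc) {
  state_require(state, c("k", "max", "data_size"))
  k <- state_get(state, "k"); maxn <- state_get(state, "max")
  ds <- state_get(state, "data_size")
  w_n <- wn_of(maxn)
  count <- be_to_int(cursor_take(cur, 4L, "block count"))
  blocks <- vector("list", count)
  for (i in seq_len(count)) {
    n <- if (w_n) be_to_int(cursor_take(cur, w_n, "block n")) else 1
    if (n < 1 || n > maxn) kff_stop("block", "block %d: stored n=%d outside 1..max=%d", i, n, maxn)
    seq <- parse_packed(cur, n + k - 1, enc, "block sequence")
    blocks[[i]] <- kff_block(seq, cursor_take(cur, n * ds, "block data"))
  }
  kff_section_r(blocks)
}

parse_section_m <- function(cur, state, enc) {
  state_require(state, c("k", "max", "data_size", "m"))
  k <- state_get(state, "k"); maxn <- state_get(state, "max")
  ds <- state_get(state, "data_size"); m <- state_get(state, "m")
  w_n <- wn_of(maxn)
  w_p <- wp_of(maxn, k, m)
  minimizer <- parse_packed(cur, m, enc, "minimizer")
  count <- be_to_int(cursor_take(cur, 4L, "block count"))
  blocks <- vector("list", count)
  for (i in seq_len(count)) {
    n <- if (w_n) be_to_int(cursor_take(cur, w_n, "block n")) else 1
    if (n < 1 || n > maxn) kff_stop("block", "block %d: stored n=%d outside 1..max=%d", i, n, maxn)
    pos <- be_to_int(cursor_take(cur, w_p, "minimizer position"))
    skel_nt <- n + k - 1 - m
    if (skel_nt < 0) kff_stop("block", "block %d: negative skeleton length", i)
    skeleton <- parse_packed(cur, skel_nt, enc, "skeleton")
    if (pos > skel_nt) kff_stop("block", "block %d: minimizer position %d out of range 0..%d",
                                i, pos, skel_nt)
    blocks[[i]] <- kff_mblock(skeleton, pos, cursor_take(cur, n * ds, "block data"))
  }
  kff_section_m(minimizer, blocks)
}

parse_section_i <- function(cur) {
  count <- be_to_int(cursor_take(cur, 4L, "index entry count"))
  types <- character(count)
  offs <- numeric(count)
  for (i in seq_len(count)) {
    types[i] <- rawToChar(cursor_take(cur, 1L, "index entry type"))
    offs[i] <- be8_to_sint(cursor_take(cur, 8L, "index entry offset"))
  }
  nxt <- be8_to_sint(cursor_take(cur, 8L, "next index offset"))
  kff_section_i(data.frame(section_type = types, relative_offset = offs,
                           stringsAsFactors = FALSE), nxt)
}

#' Parse KFF bytes into the in-memory model
#'
#' Parses the header, then sections sequentially in file order, updating the
#' variable state as V sections pass. A missing end-magic raises a warning
#' (truncated streams are tolerated); a wrong leading magic, an unknown
#' section-type byte, or a truncated section is an error.
#'
#' @param bytes Raw vector holding a complete KFF stream.
#' @return A [kff_file()]. Each parsed section carries attributes
#'   `byte_start` / `byte_length` (0-based absolute offsets) and, for R/M
#'   sections, `vars` (the governing variable snapshot). The file carries
#'   attribute `end_magic` (logical).
#' @export
kff_parse <- function(bytes) {
  cur <- new_cursor(as.raw(bytes))
  header <- parse_header(cur)
  state <- new_state()
  sections <- list()
  end_magic <- FALSE
  repeat {
    rem <- cursor_remaining(cur)
    if (rem == 0L) {
      warning("KFF stream ends without end-magic", call. = FALSE)
      break
    }
    if (rem == 3L && identical(cur$bytes[cur$pos:(cur$pos + 2L)], KFF_MAGIC)) {
      end_magic <- TRUE
      break
    }
    start0 <- cur$pos - 1L
    type <- rawToChar(cursor_take(cur, 1L, "section type"))
    section <- switch(type,
      v = parse_section_v(cur),
      r = parse_section_r(cur, state, header$encoding),
      m = parse_section_m(cur, state, header$encoding),
      i = parse_section_i(cur),
      kff_stop("section", "unknown section type byte 0x%02x at offset %d",
               as.integer(charToRaw(type)), start0)
    )
    attr(section, "byte_start") <- start0
    attr(section, "byte_length") <- cur$pos - 1L - start0
    if (type == "v") {
      state_update(state, section$vars)
    } else if (type %in% c("r", "m")) {
      attr(section, "vars") <- state$vars
    }
    sections[[length(sections) + 1L]] <- section
  }
  out <- kff_file(header, sections)
  attr(out, "end_magic") <- end_magic
  attr(out, "file_size") <- length(bytes)
  out
}

#' Read a KFF file from disk
#'
#' @param path Path to a KFF file.
#' @return A [kff_file()]; see [kff_parse()].
#' @export
kff_read <- function(path) {
  if (!file.exists(path)) kff_stop("io", "cannot read '%s'", path)
  kff_parse(readBin(path, "raw", n = file.size(path)))
}

# coerce path / raw / model to a model
as_kff_file <- function(x) {
  if (inherits(x, "kff_file")) return(x)
  if (is.raw(x)) return(kff_parse(x))
  if (is.character(x) && length(x) == 1L) return(kff_read(x))
  kff_stop("usage", "expected a kff_file, raw vector or file path")
}

#' Append a fresh section index to a file
#'
#' Rewrites the file with one terminal I section (before the end-magic)
#' whose entries resolve to every other section; any pre-existing index
#' sections are dropped first. The k-mer content is unchanged.
#'
#' @param x A [kff_file()], raw vector or path.
#' @return The indexed [kff_file()].
#' @export
kff_build_index <- function(x) {
  file <- as_kff_file(x)
  sections <- Filter(function(s) s$type != "i", file$sections)
  stripped <- kff_file(file$header, sections)
  bytes <- kff_serialize(stripped)
  off <- attr(bytes, "section_offsets")
  index_start <- length(bytes) - 3  # where the end-magic sat
  index_size <- 1 + 4 + 9 * nrow(off) + 8
  index_end <- index_start + index_size
  idx <- kff_section_i(data.frame(
    section_type = off$type,
    relative_offset = off$start - index_end,
    stringsAsFactors = FALSE
  ))
  kff_file(file$header, c(sections, list(idx)))
}
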