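# Nucleotide alphabet handling: the 2-bit codec every packed field uses,
# reverse complement and canonical form.
#
# Packing convention (normative for this dialect): nucleotides go 4 per byte
# in sequence order and the FINAL nucleotide occupies the two least
# significant bits of the last payload byte. When length %% 4 != 0 the unused
# (padding) bit pairs sit in the most significant bits of the first byte and
# are zero. Under an order-preserving encoding this makes numeric comparison
# of equal-length packed k-mers coincide with lexicographic comparison.

#' Build a 2-bit nucleotide encoding
#'
#' A KFF file declares which 2-bit code each nucleotide maps to; any
#' permutation of 0..3 over A, C, G, T is legal. The default is the
#' widely used example encoding A:0, C:1, G:3, T:2.
#'
#' @param a,c,g,t Integer codes in 0..3, jointly a permutation.
#' @return An object of class `kff_encoding`: a named integer vector with
#'   elements `A`, `C`, `G`, `T`.
#' @examples
#' kff_encoding()           # A:0 C:1 G:3 T:2
#' kff_encoding(0, 1, 2, 3) # identity order
#' @export
kff_encoding <- function(a = 0L, c = 1L, g = 3L, t = 2L) {
  codes <- suppressWarnings(as.integer(c(a, c, g, t)))
  if (anyNA(codes) || !identical(sort(codes), 0:3)) {
    kff_stop("encoding", "encoding codes must be a permutation of 0..3 (got %s)",
             paste(c(a, c, g, t), collapse = ","))
  }
  names(codes) <- c("A", "C", "G", "T")
  class(codes) <- "kff_encoding"
  codes
}

#' @export
print.kff_encoding <- function(x, ...) {
  cat(sprintf("<kff_encoding A:%d C:%d G:%d T:%d>\n", x[["A"]], x[["C"]], x[["G"]], x[["T"]]))
  invisible(x)
}

# letters indexed by code + 1
decode_table <- function(enc) {
  dec <- character(4)
  dec[as.integer(enc) + 1L] <- names(enc)
  dec
}

# single byte packing codes of A,C,G,T from most to least significant bit pair
encoding_to_byte <- function(enc) {
  as.raw(enc[["A"]] * 64L + enc[["C"]] * 16L + enc[["G"]] * 4L + enc[["T"]])
}

byte_to_encoding <- function(b) {
  v <- as.integer(b)
  kff_encoding(v %/% 64L, (v %/% 16L) %% 4L, (v %/% 4L) %% 4L, v %% 4L)
}

# Upper-case and verify ACGT-only; returns the cleaned string(s).
# KFF has no ambiguity codes: N (or anything else) is an error.
check_sequence <- function(seq, what = "sequence") {
  seq <- toupper(seq)
  bad <- regexpr("[^ACGT]", seq)
  hit <- which(bad > 0L)
  if (length(hit)) {
    kff_stop("alphabet", "%s contains non-ACGT character '%s' at position %d",
             what, substr(seq[hit[1]], bad[hit[1]], bad[hit[1]]), bad[hit[1]])
  }
  seq
}

seq_to_codes <- function(seq, enc) {
  if (nchar(seq) == 0) return(integer(0))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  unname(enc[chars])
}

pack_codes <- function(codes) {
  if (length(codes) == 0) return(raw(0))
  pad <- (-length(codes)) %% 4L
  if (pad) codes <- c(integer(pad), codes)
  m <- matrix(codes, nrow = 4L)
  as.raw(m[1L, ] * 64L + m[2L, ] * 16L + m[3L, ] * 4L + m[4L, ])
}

unpack_codes <- function(payload, length) {
  if (length == 0) return(integer(0))
  v <- as.integer(payload)
  codes <- as.integer(rbind(v %/% 64L, (v %/% 16L) %% 4L, (v %/% 4L) %% 4L, v %% 4L))
  codes[(length(codes) - length + 1L):length(codes)]
}

#' Pack a nucleotide sequence into 2 bits per base
#'
#' @param seq A single A/C/G/T string (lower case accepted, upper-cased).
#' @param enc A [kff_encoding()].
#' @return An object of class `kff_packed`: a list with `payload` (raw
#'   vector of exactly `ceiling(length/4)` bytes) and `length` (nucleotide
#'   count). Padding bit pairs, when present, are the most significant bits
#'   of the first byte and are zero.
#' @examples
#' p <- encode_sequence("ACTG")
#' p$payload # 0x1b under the default encoding
#' @seealso [decode_sequence()]
#' @export
encode_sequence <- function(seq, enc = kff_encoding()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- check_sequence(seq)
  structure(list(payload = pack_codes(seq_to_codes(seq, enc)), length = nchar(seq)),
            class = "kff_packed")
}

#' Unpack a 2-bit packed sequence
#'
#' @param p A `kff_packed` object, or a raw vector (then `length` must be
#'   given).
#' @param enc The [kff_encoding()] the payload was packed under.
#' @param length Nucleotide count when `p` is a bare raw vector.
#' @return The nucleotide string; `decode_sequence(encode_sequence(x)) == x`.
#' @export
decode_sequence <- function(p, enc = kff_encoding(), length = NULL) {
  if (inherits(p, "kff_packed")) {
    payload <- p$payload
    length <- p$length
  } else {
    payload <- as.raw(p)
    if (is.null(length)) kff_stop("usage", "length is required for a raw payload")
  }
  need <- ceiling(length / 4)
  if (base::length(payload) < need) {
    kff_stop("truncation", "payload has %d byte(s) but %d nucleotides need %d",
             base::length(payload), length, need)
  }
  if (base::length(payload) > need) {
    kff_stop("truncation", "payload has %d byte(s); expected exactly %d",
             base::length(payload), need)
  }
  if (length == 0) return("")
  paste(decode_table(enc)[unpack_codes(payload, length) + 1L], collapse = "")
}

# Vectorised packing of equal-length sequences; returns one raw vector of
# concatenated per-sequence payloads. Hot path for one-k-mer-per-block files.
pack_equal_length <- function(seqs, enc) {
  n <- length(seqs)
  L <- nchar(seqs[1L])
  if (L == 0 || n == 0) return(raw(0))
  chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  codes <- unname(enc[chars])
  if (anyNA(codes)) kff_stop("alphabet", "non-ACGT character in sequence set")
  pad <- (-L) %% 4L
  m <- matrix(codes, nrow = L)
  if (pad) m <- rbind(matrix(0L, nrow = pad, ncol = n), m)
  first <- seq(1L, nrow(m), by = 4L)
  bytes <- m[first, , drop = FALSE] * 64L + m[first + 1L, , drop = FALSE] * 16L +
    m[first + 2L, , drop = FALSE] * 4L + m[first + 3L, , drop = FALSE]
  as.raw(bytes)
}

#' Reverse complement
#'
#' Watson-Crick reverse complement of one or more A/C/G/T strings.
#' An involution: applying it twice returns the input.
#'
#' @param seq Character vector of A/C/G/T strings.
#' @return Character vector of the same length.
#' @export
reverse_complement <- function(seq) {
  seq <- check_sequence(seq)
  comp <- chartr("ACGT", "TGCA", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

#' Canonical form of a k-mer
#'
#' The lexicographically smaller (letter order A<C<G<T, independent of any
#' file encoding) of a k-mer and its reverse complement, so both strands map
#' to one representative. Canonicity is a property of the k-mer set and does
#' not change when a file is re-encoded.
#'
#' @param kmer Character vector of A/C/G/T strings.
#' @return Character vector of canonical forms; idempotent.
#' @export
canonical_kmer <- function(kmer) {
  kmer <- check_sequence(kmer)
  rc <- reverse_complement(kmer)
  ifelse(kmer <= rc, kmer, rc)
}
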