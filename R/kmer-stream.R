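# Consumer-facing iteration: (k-mer, data) records out of any KFF file in
# file order, whatever the section mix. KFF is a sequential format (no
# random access), so this is the canonical way to consume a file.

#' Length-k windows of a sequence
#'
#' @param sequence A/C/G/T string of length >= k.
#' @param k Window size.
#' @return Character vector of the `nchar(sequence) - k + 1` windows, left
#'   to right.
#' @examples
#' kmers_of_sequence("ACTAAACTGATG", 10)
#' @export
kmers_of_sequence <- function(sequence, k) {
  L <- nchar(sequence)
  if (L < k) kff_stop("length", "sequence of length %d is shorter than k=%d", L, k)
  substring(sequence, 1:(L - k + 1), k:L)
}

# split a block's data payload into one raw vector per k-mer
split_data <- function(data, n, ds) {
  if (ds == 0) return(rep(list(raw(0)), n))
  m <- matrix(data, nrow = ds)
  lapply(seq_len(n), function(i) m[, i])
}

#' Decode big-endian counts from per-k-mer payloads
#'
#' @param data List of raw vectors (as in the `data` column of
#'   [kff_kmers()]).
#' @return Numeric vector of unsigned big-endian values (exact below 2^53).
#' @export
decode_count <- function(data) {
  vapply(data, be_to_int, numeric(1))
}

#' Encode counts as fixed-width big-endian payloads
#'
#' @param x Numeric vector of non-negative counts.
#' @param width Payload width in bytes (the file's `data_size`).
#' @return List of raw vectors of length `width`.
#' @export
encode_count <- function(x, width) {
  lapply(x, int_to_be, width = width)
}

#' Stream all (k-mer, data) records of a KFF file
#'
#' Walks sections in file order: R blocks yield their length-k windows with
#' their payloads; M blocks are first reconstructed by re-inserting the
#' section minimizer; V sections update `k`/`max`/`data_size`/`m`
#' mid-stream; I sections are skipped. No ordering is imposed beyond file
#' order.
#'
#' @param x A [kff_file()], raw vector or path.
#' @return A data.frame with columns `kmer` (character), `count` (numeric;
#'   big-endian decode of the payload, `NA` when `data_size` is 0) and
#'   `data` (list of raw vectors of `data_size` bytes).
#' @examples
#' f <- kff_toy_file()
#' kff_kmers(f)$kmer
#' @export
kff_kmers <- function(x) {
  file <- as_kff_file(x)
  state <- new_state()
  kmers <- list()
  data <- list()
  for (section in file$sections) {
    if (section$type == "v") {
      state_update(state, section$vars)
      next
    }
    if (section$type == "i") next
    state_require(state, c("k", "max", "data_size",
                           if (section$type == "m") "m"))
    k <- state_get(state, "k")
    ds <- state_get(state, "data_size")
    for (b in section$blocks) {
      seqs <- if (section$type == "r") b$sequence else
        reconstruct_sequence(b$skeleton, section$minimizer, b$minimizer_position)
      w <- kmers_of_sequence(seqs, k)
      n <- length(w)
      if (length(b$data) != n * ds) {
        kff_stop("block", "block carries %d data byte(s) for %d k-mer(s) (data_size=%d)",
                 length(b$data), n, ds)
      }
      kmers[[length(kmers) + 1L]] <- w
      data[[length(data) + 1L]] <- split_data(b$data, n, ds)
    }
  }
  kmer <- unlist(kmers, use.names = FALSE)
  if (is.null(kmer)) kmer <- character(0)
  payload <- unlist(data, recursive = FALSE, use.names = FALSE)
  if (is.null(payload)) payload <- list()
  counts <- if (length(payload)) {
    sizes <- lengths(payload)
    ifelse(sizes == 0, NA_real_, decode_count(payload))
  } else numeric(0)
  out <- data.frame(kmer = kmer, count = counts, stringsAsFactors = FALSE)
  out$data <- payload
  out
}
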