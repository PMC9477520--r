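# In-memory model of every KFF construct: header, V/R/M/I sections, blocks.
#
# A file is a header plus an ordered list of sections. V sections carry the
# running variable state (k, max, data_size, m) that gates how following R/M
# sections are laid out; R sections store overlapping-k-mer sequences
# explicitly; M sections store super-k-mer skeletons with the shared
# minimizer deleted and only its insertion position kept; I sections index
# section positions (never k-mers).

#' KFF file header
#'
#' @param encoding A [kff_encoding()] governing all packed sequences.
#' @param unique_kmers Flag: no k-mer occurs twice in the file.
#' @param canonical_kmers Flag: every stored k-mer is in canonical form.
#' @param metadata Free bytes (raw vector, or a string converted to bytes).
#' @param version Integer `c(major, minor)`; this package writes 1.0.
#' @return An object of class `kff_header`.
#' @export
kff_header <- function(encoding = kff_encoding(), unique_kmers = FALSE,
                       canonical_kmers = FALSE, metadata = raw(0),
                       version = c(1L, 0L)) {
  if (!inherits(encoding, "kff_encoding")) encoding <- do.call(kff_encoding, as.list(encoding))
  if (is.character(metadata)) metadata <- charToRaw(metadata)
  structure(list(
    version_major = as.integer(version[1]), version_minor = as.integer(version[2]),
    encoding = encoding,
    unique_kmers = isTRUE(unique_kmers), canonical_kmers = isTRUE(canonical_kmers),
    metadata = as.raw(metadata)
  ), class = "kff_header")
}

#' @export
print.kff_header <- function(x, ...) {
  cat(sprintf("<kff_header v%d.%d A:%d C:%d G:%d T:%d unique=%d canonical=%d metadata=%dB>\n",
              x$version_major, x$version_minor,
              x$encoding[["A"]], x$encoding[["C"]], x$encoding[["G"]], x$encoding[["T"]],
              x$unique_kmers, x$canonical_kmers, length(x$metadata)))
  invisible(x)
}

#' Variable (V) section
#'
#' Defines named unsigned integers used by following sections. `k`, `max`
#' and `data_size` must be defined before the first R or M section; `m`
#' additionally before the first M section. Later definitions override
#' earlier ones.
#'
#' @param ... Named scalar values, e.g. `kff_section_v(k = 10, max = 255,
#'   data_size = 0, m = 8)`.
#' @return An object of class `kff_section_v` (and `kff_section`).
#' @export
kff_section_v <- function(...) {
  vars <- c(...)
  if (length(vars) && (is.null(names(vars)) || any(!nzchar(names(vars))))) {
    kff_stop("variable", "every variable needs a non-empty name")
  }
  vars <- vapply(vars, as.numeric, numeric(1))
  if (any(vars < 0)) kff_stop("variable", "variable values must be non-negative")
  structure(list(type = "v", vars = vars), class = c("kff_section_v", "kff_section"))
}

#' Sequence block for an R section
#'
#' A block stores `n` overlapping k-mers as one explicit sequence of
#' `n + k - 1` nucleotides plus `n` fixed-width data payloads.
#'
#' @param sequence A/C/G/T string of length `n + k - 1`.
#' @param data Raw vector of `n * data_size` bytes, in k-mer order.
#' @param n Optional declared k-mer count; defaults to the count implied by
#'   the sequence length when the block is serialized.
#' @return An object of class `kff_block`.
#' @export
kff_block <- function(sequence, data = raw(0), n = NULL) {
  structure(list(sequence = check_sequence(sequence), data = as.raw(data),
                 n = if (!is.null(n)) as.numeric(n)),
            class = "kff_block")
}

#' Raw-sequence (R) section
#'
#' @param blocks A [kff_block()] or list of them.
#' @return An object of class `kff_section_r` (and `kff_section`).
#' @export
kff_section_r <- function(blocks = list()) {
  if (inherits(blocks, "kff_block")) blocks <- list(blocks)
  structure(list(type = "r", blocks = blocks), class = c("kff_section_r", "kff_section"))
}

#' Minimizer block for an M section
#'
#' Stores a super-k-mer with the section's shared minimizer deleted: the
#' remaining `n + k - 1 - m` nucleotides (the skeleton) plus the 0-based
#' position at which the minimizer is re-inserted to reconstruct the full
#' sequence.
#'
#' @param skeleton A/C/G/T string (may be empty when the single k-mer equals
#'   its minimizer).
#' @param minimizer_position 0-based insertion position, in
#'   `0..nchar(skeleton)`.
#' @param data Raw vector of `n * data_size` bytes.
#' @param n Optional declared k-mer count (defaults from skeleton length).
#' @return An object of class `kff_mblock`.
#' @export
kff_mblock <- function(skeleton, minimizer_position, data = raw(0), n = NULL) {
  skeleton <- if (nchar(skeleton)) check_sequence(skeleton) else ""
  structure(list(skeleton = skeleton,
                 minimizer_position = as.numeric(minimizer_position),
                 data = as.raw(data),
                 n = if (!is.null(n)) as.numeric(n)),
            class = "kff_mblock")
}

#' Minimizer (M) section
#'
#' All blocks of an M section share one m-mer, stored once in the section
#' header; each block only records where to re-insert it.
#'
#' @param minimizer The shared m-mer.
#' @param blocks A [kff_mblock()] or list of them.
#' @return An object of class `kff_section_m` (and `kff_section`).
#' @export
kff_section_m <- function(minimizer, blocks = list()) {
  if (inherits(blocks, "kff_mblock")) blocks <- list(blocks)
  structure(list(type = "m", minimizer = check_sequence(minimizer), blocks = blocks),
            class = c("kff_section_m", "kff_section"))
}

#' Index (I) section
#'
#' Positions of other sections, as signed byte offsets relative to the first
#' byte after this index section; a trailing offset chains to the next index
#' section (0 = none). Indexes sections, never k-mers.
#'
#' @param entries `data.frame` with columns `section_type` (one of
#'   v/r/m/i) and `relative_offset` (signed).
#' @param next_index Signed offset to the next index section, 0 for none.
#' @return An object of class `kff_section_i` (and `kff_section`).
#' @export
kff_section_i <- function(entries = data.frame(section_type = character(),
                                               relative_offset = numeric()),
                          next_index = 0) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (nrow(entries) && !all(entries$section_type %in% c("v", "r", "m", "i"))) {
    kff_stop("index", "index entry types must be one of v, r, m, i")
  }
  structure(list(type = "i", entries = entries, next_index = as.numeric(next_index)),
            class = c("kff_section_i", "kff_section"))
}

#' In-memory KFF file
#'
#' @param header A [kff_header()].
#' @param sections Ordered list of `kff_section` objects.
#' @return An object of class `kff_file`.
#' @export
kff_file <- function(header = kff_header(), sections = list()) {
  if (inherits(sections, "kff_section")) sections <- list(sections)
  structure(list(header = header, sections = sections), class = "kff_file")
}

#' @export
print.kff_file <- function(x, ...) {
  types <- vapply(x$sections, function(s) s$type, character(1))
  cat(sprintf("<kff_file: %d section(s)%s>\n", length(types),
              if (length(types)) paste0(" [", paste(types, collapse = ""), "]") else ""))
  print(x$header)
  invisible(x)
}

#' Reconstruct a super-k-mer sequence from skeleton and minimizer
#'
#' Inserts the minimizer into the skeleton at the stored 0-based position:
#' `skeleton[0:pos] + minimizer + skeleton[pos:]`. The exact inverse of
#' deleting `m` letters at that position.
#'
#' @param skeleton The stored skeleton string (possibly empty).
#' @param minimizer The section's m-mer.
#' @param position 0-based insertion position in `0..nchar(skeleton)`.
#' @return The reconstructed sequence of `nchar(skeleton) + nchar(minimizer)`
#'   nucleotides.
#' @examples
#' reconstruct_sequence("ACTG", "AAACTGAT", 3) # "ACTAAACTGATG"
#' @export
reconstruct_sequence <- function(skeleton, minimizer, position) {
  ls <- nchar(skeleton)
  if (position < 0 || position > ls) {
    kff_stop("block", "minimizer position %d out of range 0..%d", position, ls)
  }
  paste0(substr(skeleton, 1, position), minimizer, substr(skeleton, position + 1, ls))
}

# variable state helpers -----------------------------------------------------

new_state <- function() {
  st <- new.env(parent = emptyenv())
  st$vars <- numeric(0)
  st
}

state_update <- function(state, vars) {
  for (nm in names(vars)) state$vars[[nm]] <- vars[[nm]]
  invisible(state)
}

state_get <- function(state, name) {
  if (!name %in% names(state$vars)) return(NULL)
  state$vars[[name]]
}

state_require <- function(state, names, error_class = "variable") {
  missing <- setdiff(names, names(state$vars))
  if (length(missing)) {
    kff_stop(error_class, "variable(s) %s must be defined by a V section first",
             paste(missing, collapse = ", "))
  }
  invisible(state)
}

# derived k-mer count of a block under the current k (and m for M blocks)
block_n <- function(block, k, m = NULL) {
  if (inherits(block, "kff_mblock")) nchar(block$skeleton) - k + 1 + m
  else nchar(block$sequence) - k + 1
}

# windows of a section, for validation and streaming
section_kmers <- function(section, k, m = NULL) {
  if (inherits(section, "kff_section_r")) {
    unlist(lapply(section$blocks, function(b) kmers_of_sequence(b$sequence, k)),
           use.names = FALSE)
  } else if (inherits(section, "kff_section_m")) {
    unlist(lapply(section$blocks, function(b) {
      kmers_of_sequence(reconstruct_sequence(b$skeleton, section$minimizer,
                                             b$minimizer_position), k)
    }), use.names = FALSE)
  } else {
    character(0)
  }
}

#' Validate one section against the running variable state
#'
#' Checks the structural invariants of a section: declared against derived
#' k-mer counts, block bounds (`1 <= n <= max`), data payload sizes,
#' minimizer length and insertion position, and -- when the header flags
#' request it -- per-section k-mer uniqueness and canonical form.
#' Violations are returned as data, not raised.
#'
#' @param section A `kff_section` object.
#' @param state Named list or numeric vector with the governing variables
#'   (`k`, `max`, `data_size`, and `m` for M sections).
#' @param header The file's [kff_header()] (for the uniqueness/canonicity
#'   flags).
#' @return Character vector of violation messages; empty when the section is
#'   well formed.
#' @export
validate_section <- function(section, state, header = kff_header()) {
  vars <- if (is.environment(state)) state$vars else unlist(state)
  v <- character(0)
  add <- function(msg, ...) v <<- c(v, sprintf(msg, ...))

  if (inherits(section, "kff_section_v")) {
    if (length(section$vars) && any(!nzchar(names(section$vars)))) add("unnamed variable")
    return(v)
  }
  if (inherits(section, "kff_section_i")) {
    bad <- which(!section$entries$section_type %in% c("v", "r", "m", "i"))
    for (i in bad) add("index entry %d has unknown section type '%s'", i,
                      section$entries$section_type[i])
    return(v)
  }

  need <- c("k", "max", "data_size", if (inherits(section, "kff_section_m")) "m")
  miss <- setdiff(need, names(vars))
  if (length(miss)) {
    add("variable(s) %s undefined before section", paste(miss, collapse = ", "))
    return(v)
  }
  k <- vars[["k"]]; maxn <- vars[["max"]]; ds <- vars[["data_size"]]
  m <- if (inherits(section, "kff_section_m")) vars[["m"]] else NULL

  if (inherits(section, "kff_section_m")) {
    if (nchar(section$minimizer) != m) {
      add("minimizer '%s' has length %d, expected m=%d", section$minimizer,
          nchar(section$minimizer), m)
    }
  }

  for (i in seq_along(section$blocks)) {
    b <- section$blocks[[i]]
    n <- block_n(b, k, m)
    if (inherits(b, "kff_mblock")) {
      if (b$minimizer_position < 0 || b$minimizer_position > nchar(b$skeleton)) {
        add("block %d: minimizer position %d out of range 0..%d", i,
            b$minimizer_position, nchar(b$skeleton))
        next
      }
    }
    if (!is.null(b$n) && b$n != n) {
      add("block %d: window count mismatch (declared n=%d, sequence implies %d)",
          i, b$n, n)
    }
    if (n < 1) add("block %d: empty block (sequence shorter than k)", i)
    if (n > maxn) add("block %d: n=%d exceeds max=%d", i, n, maxn)
    if (n >= 1 && length(b$data) != n * ds) {
      add("block %d: data has %d byte(s), expected n*data_size = %d", i,
          length(b$data), n * ds)
    }
  }

  if (!length(v) && (header$unique_kmers || header$canonical_kmers)) {
    kmers <- tryCatch(section_kmers(section, k, m), error = function(e) NULL)
    if (!is.null(kmers)) {
      if (header$unique_kmers) {
        for (d in unique(kmers[duplicated(kmers)])) add("duplicate k-mer %s", d)
      }
      if (header$canonical_kmers) {
        nc <- unique(kmers[kmers != canonical_kmer(kmers)])
        for (x in nc) add("non-canonical k-mer %s", x)
      }
    }
  }
  v
}
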