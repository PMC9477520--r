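# kff-tools-style file manipulation: validate, inspect, text conversion,
# merge, split, index. Every rewriting command preserves the (k-mer, data)
# multiset.

resolve_bytes <- function(x) {
  if (is.raw(x)) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) kff_stop("io", "cannot read '%s'", x)
    return(readBin(x, "raw", n = file.size(x)))
  }
  if (inherits(x, "kff_file")) return(kff_serialize(x))
  kff_stop("usage", "expected a kff_file, raw vector or file path")
}

#' Validate a KFF file
#'
#' Parses the file and checks every section's invariants against the
#' running variable state, plus -- for index sections -- that every entry
#' offset resolves to a byte equal to the declared section-type character.
#' A missing end-magic is a warning, not a failure.
#'
#' @param x A [kff_file()], raw vector or path.
#' @return List with `status` (0 valid, 1 violations found, 3 parse/I-O
#'   failure), `violations` (data.frame of `section`, `offset`, `message`)
#'   and `warnings` (character).
#' @export
kff_validate <- function(x) {
  warns <- character(0)
  bytes <- tryCatch(resolve_bytes(x), kff_error = function(e) e)
  if (inherits(bytes, "kff_error")) {
    return(list(status = 3L, violations = viol_df("<file>", NA, conditionMessage(bytes)),
                warnings = warns))
  }
  file <- withCallingHandlers(
    tryCatch(kff_parse(bytes), error = function(e) e),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (inherits(file, "error")) {
    return(list(status = 3L, violations = viol_df("<parse>", NA, conditionMessage(file)),
                warnings = warns))
  }

  v <- viol_df(character(0), numeric(0), character(0))
  state <- new_state()
  for (i in seq_along(file$sections)) {
    s <- file$sections[[i]]
    start <- attr(s, "byte_start")
    msgs <- validate_section(s, state, file$header)
    if (s$type == "v") state_update(state, s$vars)
    if (s$type == "i") msgs <- c(msgs, check_index_section(s, bytes))
    if (length(msgs)) v <- rbind(v, viol_df(sprintf("%s@%d", s$type, start), start, msgs))
  }
  list(status = if (nrow(v)) 1L else 0L, violations = v, warnings = warns)
}

viol_df <- function(section, offset, message) {
  data.frame(section = section, offset = offset, message = message,
             stringsAsFactors = FALSE)
}

check_index_section <- function(s, bytes) {
  msgs <- character(0)
  after <- attr(s, "byte_start") + attr(s, "byte_length")
  resolve <- function(rel, expect, what) {
    t0 <- after + rel
    if (t0 < 0 || t0 >= length(bytes)) {
      return(sprintf("broken index: %s offset %d resolves outside the file", what, rel))
    }
    got <- rawToChar(bytes[t0 + 1])
    if (got != expect) {
      return(sprintf("broken index: %s offset %d lands on '%s', expected '%s'",
                     what, rel, got, expect))
    }
    character(0)
  }
  for (i in seq_len(nrow(s$entries))) {
    msgs <- c(msgs, resolve(s$entries$relative_offset[i], s$entries$section_type[i],
                            sprintf("entry %d", i)))
  }
  if (s$next_index != 0) msgs <- c(msgs, resolve(s$next_index, "i", "next-index"))
  msgs
}

#' File statistics
#'
#' Streams the file and reports its k-mer count, per-type section counts,
#' byte size, and bits per k-mer -- the total file bits divided by the
#' number of stored k-mers -- both as-is and with the data payload bytes
#' removed.
#'
#' @param x A [kff_file()], raw vector or path.
#' @return An object of class `kff_stats`: a list with `kmer_count`,
#'   `section_counts`, `file_bytes`, `data_bytes`, `bits_per_kmer`,
#'   `bits_per_kmer_no_data` (the latter two `NA` for an empty file).
#' @export
kff_instr <- function(x) {
  bytes <- resolve_bytes(x)
  file <- suppressWarnings(kff_parse(bytes))
  records <- kff_kmers(file)
  types <- vapply(file$sections, function(s) s$type, character(1))
  counts <- vapply(c("v", "r", "m", "i"), function(t) sum(types == t), numeric(1))
  n <- nrow(records)
  data_bytes <- sum(lengths(records$data))
  structure(list(
    kmer_count = n,
    section_counts = counts,
    file_bytes = length(bytes),
    data_bytes = data_bytes,
    bits_per_kmer = if (n > 0) 8 * length(bytes) / n else NA_real_,
    bits_per_kmer_no_data = if (n > 0) 8 * (length(bytes) - data_bytes) / n else NA_real_
  ), class = "kff_stats")
}

#' @export
print.kff_stats <- function(x, ...) {
  cat(sprintf("k-mers:    %d\n", x$kmer_count))
  cat(sprintf("sections:  v=%d r=%d m=%d i=%d\n", x$section_counts[["v"]],
              x$section_counts[["r"]], x$section_counts[["m"]], x$section_counts[["i"]]))
  cat(sprintf("bytes:     %d (%d data payload)\n", x$file_bytes, x$data_bytes))
  if (is.na(x$bits_per_kmer)) {
    cat("bits/kmer: n/a\n")
  } else {
    cat(sprintf("bits/kmer: %.2f (%.2f omitting data)\n",
                x$bits_per_kmer, x$bits_per_kmer_no_data))
  }
  invisible(x)
}

#' Build a KFF file from a plain-text k-mer dump
#'
#' Reads `KMER<TAB>COUNT` lines (the dump format of common k-mer counters;
#' the count column is optional when `data_size` is 0, and gzip-compressed
#' input is read transparently by file extension) and writes a naive layout:
#' one k-mer per block.
#'
#' @param input Path to a text file, or a character vector of lines.
#' @param output Optional path for the KFF file.
#' @param k K-mer size; inferred from the first line when `NULL`.
#' @param data_size Bytes per count payload (0 = no counts stored).
#' @param encoding Output [kff_encoding()].
#' @param max Declared block bound written to the V section.
#' @param unique,canonical Header flags; `unique = TRUE` is verified and
#'   duplicate input is an error.
#' @return The [kff_file()], invisibly when `output` is given.
#' @export
kff_from_text <- function(input, output = NULL, k = NULL, data_size = 0,
                          encoding = kff_encoding(), max = 1,
                          unique = FALSE, canonical = FALSE) {
  lines <- if (length(input) == 1L && file.exists(input)) readLines(input) else input
  lines <- lines[nzchar(lines)]
  header <- kff_header(encoding, unique_kmers = unique, canonical_kmers = canonical)
  if (!length(lines)) {
    out <- kff_file(header)
    if (!is.null(output)) { kff_write(out, output); return(invisible(out)) }
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kmers <- check_sequence(vapply(parts, `[[`, character(1), 1L))
  ks <- unique(nchar(kmers))
  if (length(ks) > 1) {
    kff_stop("length", "ragged k-mer lengths in text input (%s)", paste(ks, collapse = ", "))
  }
  if (is.null(k)) k <- ks
  if (k != ks) kff_stop("length", "k-mers have length %d, expected k=%d", ks, k)
  if (unique && anyDuplicated(kmers)) {
    kff_stop("duplicate", "duplicate k-mer %s in input flagged unique",
             kmers[duplicated(kmers)][1])
  }
  if (canonical && any(kmers != canonical_kmer(kmers))) {
    kff_stop("block", "non-canonical k-mer in input flagged canonical")
  }
  if (data_size > 0) {
    counts <- suppressWarnings(as.numeric(vapply(parts, function(p) {
      if (length(p) < 2) NA_character_ else p[[2]]
    }, character(1))))
    if (anyNA(counts)) kff_stop("usage", "missing or non-numeric count with data_size=%d", data_size)
    blocks <- lapply(seq_along(kmers), function(i) {
      kff_block(kmers[i], int_to_be(counts[i], data_size))
    })
  } else {
    blocks <- lapply(kmers, kff_block)
  }
  out <- kff_file(header, list(
    kff_section_v(k = k, max = max, data_size = data_size),
    kff_section_r(blocks)
  ))
  if (!is.null(output)) { kff_write(out, output); return(invisible(out)) }
  out
}

#' Dump a KFF file as plain text
#'
#' One `KMER<TAB>COUNT` line per record in file order (bare k-mers when
#' `data_size` is 0). Counts are decoded big-endian and printed in decimal
#' for payloads up to 8 bytes, as hex beyond that.
#'
#' @param x A [kff_file()], raw vector or path.
#' @param output Optional path to write the lines to.
#' @return Character vector of lines, invisibly when `output` is given.
#' @export
kff_to_text <- function(x, output = NULL) {
  records <- kff_kmers(x)
  lines <- if (!nrow(records)) {
    character(0)
  } else {
    sizes <- lengths(records$data)
    if (all(sizes == 0)) {
      records$kmer
    } else if (all(sizes <= 8)) {
      sprintf("%s\t%.0f", records$kmer, decode_count(records$data))
    } else {
      hex <- vapply(records$data, function(d) paste(sprintf("%02x", as.integer(d)),
                                                    collapse = ""), character(1))
      sprintf("%s\t0x%s", records$kmer, hex)
    }
  }
  if (!is.null(output)) { writeLines(lines, output); return(invisible(lines)) }
  lines
}

# governing k / data_size values actually used by a file's R/M sections
file_kds <- function(file) {
  state <- new_state()
  ks <- numeric(0); ds <- numeric(0)
  for (s in file$sections) {
    if (s$type == "v") state_update(state, s$vars)
    if (s$type %in% c("r", "m") && length(s$blocks)) {
      state_require(state, c("k", "data_size"))
      ks <- union(ks, state_get(state, "k"))
      ds <- union(ds, state_get(state, "data_size"))
    }
  }
  list(k = ks, data_size = ds)
}

#' Merge KFF files
#'
#' Concatenates the inputs' sections (dropping index sections) into one
#' file; all inputs must share `k` and `data_size`, while encodings may
#' differ (sequences are re-encoded to the output encoding). The
#' unique/canonical flags are set only if every input sets them, and
#' uniqueness is re-verified across the merged stream (cleared when the
#' union has duplicates).
#'
#' @param inputs List of [kff_file()] objects, raw vectors or paths.
#' @param output Optional path for the merged file.
#' @param encoding Output [kff_encoding()]; default: the first input's.
#' @return The merged [kff_file()], invisibly when `output` is given.
#' @export
kff_merge <- function(inputs, output = NULL, encoding = NULL) {
  if (inherits(inputs, "kff_file") || is.character(inputs)) inputs <- as.list(inputs)
  files <- lapply(inputs, as_kff_file)
  if (!length(files)) kff_stop("usage", "nothing to merge")
  kds <- lapply(files, file_kds)
  ks <- unique(unlist(lapply(kds, `[[`, "k")))
  dss <- unique(unlist(lapply(kds, `[[`, "data_size")))
  if (length(ks) > 1) {
    kff_stop("compat", "inputs disagree on k (%s)", paste(ks, collapse = ", "))
  }
  if (length(dss) > 1) {
    kff_stop("compat", "inputs disagree on data_size (%s)", paste(dss, collapse = ", "))
  }
  if (is.null(encoding)) encoding <- files[[1]]$header$encoding
  header <- kff_header(
    encoding,
    unique_kmers = all(vapply(files, function(f) f$header$unique_kmers, logical(1))),
    canonical_kmers = all(vapply(files, function(f) f$header$canonical_kmers, logical(1))),
    metadata = files[[1]]$header$metadata
  )
  sections <- unlist(lapply(files, function(f) {
    Filter(function(s) s$type != "i", f$sections)
  }), recursive = FALSE)
  out <- kff_file(header, sections)
  if (header$unique_kmers) {
    if (anyDuplicated(kff_kmers(out)$kmer)) out$header$unique_kmers <- FALSE
  }
  if (!is.null(output)) { kff_write(out, output); return(invisible(out)) }
  out
}

#' Split a KFF file into one file per R/M section
#'
#' Each output carries a copy of the header plus a V section with the
#' governing variable state and one sequence section; concatenating the
#' outputs' streams reproduces the input stream.
#'
#' @param x A [kff_file()], raw vector or path.
#' @param out_prefix Output path prefix; files are named
#'   `<prefix>_<i>.kff`.
#' @return Character vector of the paths written.
#' @export
kff_split <- function(x, out_prefix) {
  file <- as_kff_file(x)
  state <- new_state()
  paths <- character(0)
  i <- 0L
  for (s in file$sections) {
    if (s$type == "v") { state_update(state, s$vars); next }
    if (s$type == "i") next
    state_require(state, c("k", "max", "data_size", if (s$type == "m") "m"))
    i <- i + 1L
    path <- sprintf("%s_%03d.kff", out_prefix, i)
    piece <- kff_file(file$header, list(
      do.call(kff_section_v, as.list(state$vars)), s
    ))
    kff_write(piece, path)
    paths <- c(paths, path)
  }
  paths
}

#' Index a KFF file on disk
#'
#' Appends a terminal I section resolving to every section (see
#' [kff_build_index()]).
#'
#' @param x A [kff_file()], raw vector or path.
#' @param output Optional path for the indexed file.
#' @return The indexed [kff_file()], invisibly when `output` is given.
#' @export
kff_index <- function(x, output = NULL) {
  out <- kff_build_index(x)
  if (!is.null(output)) { kff_write(out, output); return(invisible(out)) }
  out
}
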