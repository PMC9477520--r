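# Compaction: turn flat k-mer sets into space-efficient layouts.
#
# The pipeline is: greedily chain k-mers into longer overlapping sequences
# (a greedy spectrum-preserving string set, i.e. a path cover of the
# (k-1)-overlap graph), then either store the chains directly as R blocks
# (SPSS layout) or split them into super-k-mers -- maximal runs of
# consecutive k-mers sharing one minimizer occurrence -- and bucket those by
# minimizer into M sections, where the shared m-mer is stored once per
# section and deleted from every block.

#' Minimizer of a sequence
#'
#' The lexicographically smallest length-m window (letter order A<C<G<T,
#' independent of any file encoding), ties broken by leftmost occurrence.
#'
#' @param sequence A/C/G/T string of length >= m.
#' @param m Minimizer size.
#' @return List with `minimizer` (the m-mer) and `position` (0-based).
#' @examples
#' minimizer_of("ACTAAACTGATG", 8) # AAACTGAT at position 3
#' @export
minimizer_of <- function(sequence, m) {
  sequence <- check_sequence(sequence)
  if (nchar(sequence) < m) {
    kff_stop("length", "sequence of length %d is shorter than m=%d", nchar(sequence), m)
  }
  .minimizer_cpp(sequence, as.integer(m))
}

#' Split a sequence into super-k-mers
#'
#' Partitions the sequence's run of k-mers into maximal consecutive runs
#' whose per-window minimizers are the same m-mer at the same absolute
#' position. Concatenating the runs' windows reproduces the sequence's
#' windows in order, each exactly once.
#'
#' @param sequence A/C/G/T string of length >= k.
#' @param k K-mer size.
#' @param m Minimizer size, `m <= k`.
#' @return List of super-k-mers, each a list with `sequence`, `minimizer`
#'   and `minimizer_position` (0-based, relative to the super-k-mer).
#' @examples
#' split_into_superkmers("ACTAAACTGATG", k = 10, m = 8)
#' @export
split_into_superkmers <- function(sequence, k, m) {
  sequence <- check_sequence(sequence)
  if (nchar(sequence) < k) {
    kff_stop("length", "sequence of length %d is shorter than k=%d", nchar(sequence), k)
  }
  if (m > k) kff_stop("parameter", "m=%d exceeds k=%d", m, k)
  runs <- .superkmer_runs_cpp(sequence, as.integer(k), as.integer(m))
  lapply(seq_len(nrow(runs)), function(i) {
    ws <- runs[i, 1]; we <- runs[i, 2]; mp <- runs[i, 3]
    list(sequence = substr(sequence, ws + 1, we + k),
         minimizer = substr(sequence, mp + 1, mp + m),
         minimizer_position = mp - ws)
  })
}

#' Greedy spectrum-preserving string set
#'
#' Builds a set of strings whose length-k windows are exactly the input
#' k-mers, each appearing as a window of exactly one string exactly once:
#' repeatedly seed with the first unused k-mer (input order), extend
#' greedily right then left through (k-1)-overlaps to unused k-mers, taking
#' the first extension in A<C<G<T order.
#'
#' @param kmers Character vector of distinct k-mers (duplicates are an
#'   error: an SPSS is defined on a set).
#' @param k K-mer size; defaults to the length of the first k-mer.
#' @return Character vector of strings, each of length >= k.
#' @examples
#' greedy_compact(c("ACG", "CGT")) # "ACGT"
#' @export
greedy_compact <- function(kmers, k = NULL) {
  if (!length(kmers)) return(character(0))
  kmers <- check_sequence(kmers)
  if (is.null(k)) k <- nchar(kmers[1])
  tryCatch(
    .greedy_spss_cpp(kmers, as.integer(k)),
    error = function(e) {
      cls <- if (grepl("duplicate", conditionMessage(e))) "duplicate" else "length"
      kff_stop(cls, "%s", conditionMessage(e))
    }
  )
}

# chunk a run of windows first..last into pieces of at most `maxn` windows
chunk_windows <- function(first, last, maxn) {
  n <- last - first + 1
  starts <- first + seq(0, n - 1, by = maxn)
  data.frame(from = starts, to = pmin(starts + maxn - 1, last))
}

# per-k-mer payload bytes for windows [from..to] (0-based) of a chain
chain_window_data <- function(idx, from, to, data_list) {
  unlist(data_list[idx[(from + 1):(to + 1)]], use.names = FALSE)
}

#' Bucket a k-mer set into minimizer sections
#'
#' Chains the k-mers with [greedy_compact()], splits every chain into
#' super-k-mers, and groups the super-k-mers by minimizer: one M section per
#' distinct m-mer, one block per super-k-mer (split when a run exceeds
#' `max`). Data payloads stay aligned with their k-mers.
#'
#' @param kmers Character vector of distinct k-mers.
#' @param data Optional list of per-k-mer raw payloads, all the same width.
#' @param k,m K-mer and minimizer sizes.
#' @param max Block k-mer bound; default: the largest run produced, so no
#'   block is split.
#' @return List with `sections` (list of [kff_section_m()]), `max` and
#'   `data_size`.
#' @export
bucket_superkmers <- function(kmers, data = NULL, k = nchar(kmers[1]), m, max = NULL) {
  ds <- if (is.null(data) || !length(data)) 0 else length(data[[1]])
  chains <- greedy_compact(kmers, k)

  sk_min <- character(0)
  sk_blocks <- list()
  for (chain in chains) {
    runs <- .superkmer_runs_cpp(chain, as.integer(k), as.integer(m))
    idx <- NULL
    if (ds > 0) idx <- match(kmers_of_sequence(chain, k), kmers)
    for (i in seq_len(nrow(runs))) {
      ws <- runs[i, 1]; we <- runs[i, 2]; mp <- runs[i, 3]
      chunks <- if (is.null(max)) data.frame(from = ws, to = we) else
        chunk_windows(ws, we, max)
      for (j in seq_len(nrow(chunks))) {
        a <- chunks$from[j]; b <- chunks$to[j]
        full <- substr(chain, a + 1, b + k)
        pos <- mp - a
        skeleton <- paste0(substr(full, 1, pos), substr(full, pos + m + 1, nchar(full)))
        payload <- if (ds > 0) chain_window_data(idx, a, b, data) else raw(0)
        sk_min <- c(sk_min, substr(chain, mp + 1, mp + m))
        sk_blocks[[length(sk_blocks) + 1L]] <- kff_mblock(skeleton, pos, payload)
      }
    }
  }
  groups <- split(seq_along(sk_blocks), factor(sk_min, levels = unique(sk_min)))
  sections <- lapply(names(groups), function(mm) {
    kff_section_m(mm, sk_blocks[groups[[mm]]])
  })
  maxn <- if (is.null(max)) {
    if (length(sk_blocks)) {
      max(vapply(sk_blocks, function(b) nchar(b$skeleton) - k + 1 + m, numeric(1)))
    } else 1
  } else max
  list(sections = sections, max = maxn, data_size = ds)
}

# ---------------------------------------------------------------------------

records_data_size <- function(records) {
  if (!nrow(records)) return(0)
  sizes <- unique(lengths(records$data))
  if (length(sizes) > 1) {
    kff_stop("length", "mixed data payload widths (%s) cannot be recompacted",
             paste(sizes, collapse = ", "))
  }
  sizes
}

records_k <- function(records) {
  if (!nrow(records)) return(NULL)
  ks <- unique(nchar(records$kmer))
  if (length(ks) > 1) {
    kff_stop("length", "mixed k-mer lengths (%s) cannot be recompacted",
             paste(ks, collapse = ", "))
  }
  ks
}

naive_body <- function(records, k, ds) {
  blocks <- lapply(seq_len(nrow(records)), function(i) {
    kff_block(records$kmer[i], records$data[[i]])
  })
  list(kff_section_v(k = k, max = 1, data_size = ds), kff_section_r(blocks))
}

#' Compact a KFF file
#'
#' Rewrites a file's k-mer content in one of three layouts, preserving the
#' (k-mer, data) multiset exactly:
#' \describe{
#'   \item{`"superkmer"`}{greedy chaining, super-k-mer splitting, and
#'     minimizer bucketing into M sections (requires distinct k-mers; the
#'     output sets the unique-k-mers flag).}
#'   \item{`"spss"`}{greedy spectrum-preserving string set stored as
#'     overlapping R blocks (requires distinct k-mers).}
#'   \item{`"naive"`}{one k-mer per block, `max = 1` (accepts duplicates).}
#' }
#'
#' @param x A [kff_file()], raw vector or path.
#' @param mode One of `"superkmer"`, `"spss"`, `"naive"`.
#' @param m Minimizer size (superkmer mode).
#' @param max Block k-mer bound; default: large enough that no run is split.
#' @param output Optional path to write the result to.
#' @return The rewritten [kff_file()], invisibly when `output` is given.
#' @export
kff_compact <- function(x, mode = c("superkmer", "spss", "naive"), m = 10,
                        max = NULL, output = NULL) {
  mode <- match.arg(mode)
  file <- as_kff_file(x)
  records <- kff_kmers(file)
  ds <- records_data_size(records)
  k <- records_k(records)

  header <- file$header
  if (mode != "naive") {
    dup <- records$kmer[duplicated(records$kmer)]
    if (length(dup)) {
      kff_stop("duplicate", "duplicate k-mer %s: %s compaction needs a set",
               dup[1], mode)
    }
    header$unique_kmers <- TRUE
  }

  sections <- if (is.null(k)) {
    list()
  } else if (mode == "naive") {
    naive_body(records, k, ds)
  } else if (mode == "spss") {
    chains <- greedy_compact(records$kmer, k)
    idx <- if (ds > 0) match(unlist(lapply(chains, kmers_of_sequence, k = k)),
                             records$kmer) else NULL
    at <- 0
    blocks <- lapply(chains, function(chain) {
      n <- nchar(chain) - k + 1
      payload <- if (ds > 0) {
        p <- unlist(records$data[idx[(at + 1):(at + n)]], use.names = FALSE)
        at <<- at + n
        p
      } else raw(0)
      kff_block(chain, payload)
    })
    maxn <- if (is.null(max)) base::max(nchar(chains)) - k + 1 else max
    if (!is.null(max)) {
      blocks <- split_long_blocks(blocks, k, ds, max)
      maxn <- max
    }
    list(kff_section_v(k = k, max = maxn, data_size = ds), kff_section_r(blocks))
  } else {
    bk <- bucket_superkmers(records$kmer, if (ds > 0) records$data else NULL,
                            k = k, m = m, max = max)
    c(list(kff_section_v(k = k, max = bk$max, data_size = ds, m = m)), bk$sections)
  }

  out <- kff_file(header, sections)
  if (!is.null(output)) {
    kff_write(out, output)
    return(invisible(out))
  }
  out
}

# split R blocks whose window count exceeds maxn into overlapping pieces
split_long_blocks <- function(blocks, k, ds, maxn) {
  out <- list()
  for (b in blocks) {
    n <- nchar(b$sequence) - k + 1
    if (n <= maxn) {
      out[[length(out) + 1L]] <- b
      next
    }
    ch <- chunk_windows(0, n - 1, maxn)
    for (j in seq_len(nrow(ch))) {
      a <- ch$from[j]; z <- ch$to[j]
      dat <- if (ds > 0) b$data[(a * ds + 1):((z + 1) * ds)] else raw(0)
      out[[length(out) + 1L]] <- kff_block(substr(b$sequence, a + 1, z + k), dat)
    }
  }
  out
}

#' Rewrite a file with one k-mer per block
#'
#' The inverse of compaction: every (k-mer, data) record becomes its own R
#' block with `max = 1`. The k-mer multiset is unchanged; header flags are
#' preserved.
#'
#' @param x A [kff_file()], raw vector or path.
#' @param output Optional path to write the result to.
#' @return The rewritten [kff_file()], invisibly when `output` is given.
#' @export
kff_uncompact <- function(x, output = NULL) {
  file <- as_kff_file(x)
  records <- kff_kmers(file)
  ds <- records_data_size(records)
  k <- records_k(records)
  sections <- if (is.null(k)) list() else naive_body(records, k, ds)
  out <- kff_file(file$header, sections)
  if (!is.null(output)) {
    kff_write(out, output)
    return(invisible(out))
  }
  out
}
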