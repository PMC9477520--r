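# Deterministic synthetic data with the spectrum-like property: most k-mers
# arise as windows of a few long source strings, which is what makes
# overlap-based storage compress well. A sprinkle of isolated noise k-mers
# mimics sequencing-error k-mers from real counters.

#' Generate a spectrum-like k-mer set
#'
#' Draws `n_strings` uniform random A/C/G/T strings of `string_length`,
#' takes the union of their length-k windows (counts = occurrence
#' multiplicity), and adds `noise_kmers` uniform random isolated k-mers
#' (noise may collide with genuine k-mers, in which case counts merge).
#' Fully reproducible from `seed` (Mersenne-Twister; the caller's RNG state
#' is restored on exit).
#'
#' @param n_strings Number of source strings.
#' @param string_length Length of each source string (>= k).
#' @param k K-mer size.
#' @param noise_kmers Number of random isolated k-mers to add.
#' @param seed Integer seed.
#' @return List with `strings` (character vector) and `kmers` (data.frame
#'   of `kmer`, `count`; counts are >= 1 and sum to total windows + noise
#'   draws).
#' @export
generate_spectrum_set <- function(n_strings, string_length, k, noise_kmers = 0,
                                  seed = 1) {
  if (string_length < k) {
    kff_stop("parameter", "string_length=%d is shorter than k=%d", string_length, k)
  }
  if (n_strings < 0 || noise_kmers < 0) {
    kff_stop("parameter", "counts must be non-negative")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")

  draw <- function(n, len) {
    if (n == 0) return(character(0))
    letters <- sample(c("A", "C", "G", "T"), n * len, replace = TRUE)
    vapply(seq_len(n), function(i) {
      paste(letters[((i - 1) * len + 1):(i * len)], collapse = "")
    }, character(1))
  }
  strings <- draw(n_strings, string_length)
  windows <- unlist(lapply(strings, kmers_of_sequence, k = k), use.names = FALSE)
  all <- c(windows, draw(noise_kmers, k))
  u <- unique(all)
  list(strings = strings,
       kmers = data.frame(kmer = u,
                          count = tabulate(match(all, u), nbins = length(u)),
                          stringsAsFactors = FALSE))
}

# naive KFF file from a (kmer, count) table
spectrum_to_file <- function(kmers, counts = NULL, data_size = 0,
                             metadata = raw(0), unique = TRUE) {
  lines <- if (data_size > 0) sprintf("%s\t%d", kmers, counts) else kmers
  f <- kff_from_text(lines, data_size = data_size, unique = unique)
  f$header$metadata <- if (is.character(metadata)) charToRaw(metadata) else metadata
  f
}

#' The Fig-style toy file
#'
#' The classic worked example of the format: k = 10, minimizers of size 8.
#' One R section stores the 12-nucleotide sequence `ACTAAACTGATG` (three
#' overlapping 10-mers); one M section stores the same k-mer set as a
#' skeleton `ACTG` with minimizer `AAACTGAT` re-inserted at position 3.
#'
#' @return A [kff_file()] with a V, an R and an M section.
#' @export
kff_toy_file <- function() {
  kff_file(kff_header(), list(
    kff_section_v(k = 10, max = 255, data_size = 0, m = 8),
    kff_section_r(kff_block("ACTAAACTGATG")),
    kff_section_m("AAACTGAT", kff_mblock("ACTG", 3))
  ))
}

#' Write the fixture suite
#'
#' Materializes a set of small deterministic KFF files for demos and tests:
#' the toy file, plus a spectrum-like random set in naive, super-k-mer and
#' SPSS layouts, with a matching text dump and the source strings as FASTA.
#' The generator seed is recorded in each random fixture's header metadata.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed for the random fixtures.
#' @return Named character vector of the paths written.
#' @export
write_fixture_suite <- function(dir, seed = 1) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    kff_stop("io", "cannot create directory '%s'", dir)
  }
  paths <- c(
    toy = file.path(dir, "toy.kff"),
    naive = file.path(dir, "spectrum_naive.kff"),
    superkmer = file.path(dir, "spectrum_superkmer.kff"),
    spss = file.path(dir, "spectrum_spss.kff"),
    text = file.path(dir, "spectrum.tsv"),
    fasta = file.path(dir, "spectrum_sources.fasta")
  )
  kff_write(kff_toy_file(), paths[["toy"]])

  gen <- generate_spectrum_set(n_strings = 5, string_length = 400, k = 21,
                               noise_kmers = 10, seed = seed)
  meta <- sprintf("spectrum fixture seed=%d", seed)
  naive <- spectrum_to_file(gen$kmers$kmer, gen$kmers$count, data_size = 1,
                            metadata = meta)
  kff_write(naive, paths[["naive"]])
  kff_compact(naive, mode = "superkmer", m = 11, output = paths[["superkmer"]])
  kff_compact(naive, mode = "spss", output = paths[["spss"]])
  writeLines(sprintf("%s\t%d", gen$kmers$kmer, gen$kmers$count), paths[["text"]])
  writeLines(rbind(sprintf(">source_%d", seq_along(gen$strings)), gen$strings),
             paths[["fasta"]])
  paths
}
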