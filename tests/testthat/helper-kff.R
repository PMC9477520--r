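# shared fixtures-in-code and independent oracles

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

random_kmers <- function(n, k) {
  out <- character(0)
  while (length(out) < n) {
    out <- unique(c(out, vapply(seq_len(n - length(out)), function(i) random_dna(k),
                                character(1))))
  }
  out
}

all_encodings <- function() {
  perms <- expand.grid(a = 0:3, c = 0:3, g = 0:3, t = 0:3)
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  lapply(seq_len(nrow(perms)), function(i) {
    kff_encoding(perms$a[i], perms$c[i], perms$g[i], perms$t[i])
  })
}

# brute-force oracle: pack by concatenating bit pairs by hand
oracle_pack <- function(seq, enc) {
  if (nchar(seq) == 0) return(raw(0))
  codes <- unname(enc[strsplit(seq, "")[[1]]])
  bits <- unlist(lapply(codes, function(c) c(c %/% 2, c %% 2)))
  bits <- c(rep(0L, (-length(bits)) %% 8), bits)
  m <- matrix(bits, nrow = 8)
  as.raw(apply(m, 2, function(b) sum(b * 2^(7:0))))
}

# vectorised independent scan for the minimizer (implementation is C++)
oracle_minimizer <- function(seq, m) {
  L <- nchar(seq)
  windows <- substring(seq, 1:(L - m + 1), m:L)
  pos <- which(windows == min(windows))[1]
  list(minimizer = windows[pos], position = pos - 1L)
}

# multiset fingerprint of a record stream
stream_id <- function(records) {
  sort(paste(records$kmer,
             vapply(records$data, function(d) paste(as.integer(d), collapse = ","),
                    character(1))))
}

expect_same_stream <- function(a, b) {
  expect_identical(stream_id(kff_kmers(a)), stream_id(kff_kmers(b)))
}

raw_equal <- function(a, b) identical(as.vector(a), as.vector(b))

# randomized small file generator used by round-trip suites
random_kff_file <- function() {
  p <- sample(0:3)
  enc <- kff_encoding(p[1], p[2], p[3], p[4])
  k <- sample(2:64, 1)
  m <- sample(seq_len(k), 1)
  maxn <- sample(c(1, 2, 7, 255, 256, 1000), 1)
  ds <- sample(0:4, 1)
  header <- kff_header(enc, metadata = as.raw(sample(0:255, sample(0:8, 1), replace = TRUE)))
  sections <- list(kff_section_v(k = k, max = maxn, data_size = ds, m = m))
  for (s in seq_len(sample(1:3, 1))) {
    if (runif(1) < 0.5) {
      blocks <- lapply(seq_len(sample(1:4, 1)), function(i) {
        n <- sample(seq_len(min(maxn, 5)), 1)
        kff_block(random_dna(n + k - 1),
                  as.raw(sample(0:255, n * ds, replace = TRUE)))
      })
      sections <- c(sections, list(kff_section_r(blocks)))
    } else {
      minimizer <- random_dna(m)
      blocks <- lapply(seq_len(sample(1:4, 1)), function(i) {
        n <- sample(seq_len(min(maxn, 5)), 1)
        kff_mblock(random_dna(n + k - 1 - m), sample(0:(n + k - 1 - m), 1),
                   as.raw(sample(0:255, n * ds, replace = TRUE)))
      })
      sections <- c(sections, list(kff_section_m(minimizer, blocks)))
    }
  }
  kff_file(header, sections)
}
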