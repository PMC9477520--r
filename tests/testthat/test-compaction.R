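test_that("the minimizer is the smallest window, leftmost on ties", {
  expect_identical(minimizer_of("ACTAAACTGATG", 8),
                   list(minimizer = "AAACTGAT", position = 3L))
  expect_identical(minimizer_of("AAAA", 2), list(minimizer = "AA", position = 0L))
  expect_identical(minimizer_of("ACGT", 4), list(minimizer = "ACGT", position = 0L))
  expect_error(minimizer_of("ACG", 4), class = "kff_length_error")
})

test_that("minimizer_of agrees with an exhaustive scan on random sequences", {
  set.seed(41)
  for (i in 1:500) {
    m <- sample(1:12, 1)
    s <- random_dna(sample(m:60, 1))
    expect_identical(minimizer_of(s, m), oracle_minimizer(s, m))
  }
})

test_that("super-k-mer splitting partitions the window run by minimizer occurrence", {
  sk <- split_into_superkmers("ACTAAACTGATG", k = 10, m = 8)
  expect_identical(length(sk), 2L)
  expect_identical(sk[[1]],
                   list(sequence = "ACTAAACTGA", minimizer = "ACTAAACT",
                        minimizer_position = 0L))
  expect_identical(sk[[2]],
                   list(sequence = "CTAAACTGATG", minimizer = "AAACTGAT",
                        minimizer_position = 2L))

  one <- split_into_superkmers("ACGTACGT", k = 8, m = 3)
  expect_identical(length(one), 1L)
  expect_identical(one[[1]]$sequence, "ACGTACGT")
})

test_that("super-k-mers cover every window exactly once and carry their minimizer", {
  set.seed(43)
  for (i in 1:100) {
    m <- sample(2:8, 1)
    k <- sample(m:16, 1)
    s <- random_dna(sample(k:80, 1))
    sk <- split_into_superkmers(s, k, m)
    covered <- unlist(lapply(sk, function(x) kmers_of_sequence(x$sequence, k)))
    expect_identical(covered, kmers_of_sequence(s, k))
    for (x in sk) {
      expect_identical(substr(x$sequence, x$minimizer_position + 1,
                              x$minimizer_position + m), x$minimizer)
      # every window of the super-k-mer has the shared minimizer occurrence
      for (w in kmers_of_sequence(x$sequence, k)) {
        expect_identical(minimizer_of(w, m)$minimizer, x$minimizer)
      }
    }
  }
})

test_that("greedy compaction builds a spectrum-preserving string set", {
  expect_identical(greedy_compact(c("ACG", "CGT")), "ACGT")
  expect_identical(greedy_compact("AAA"), "AAA")
  expect_error(greedy_compact(c("ACG", "ACG")), class = "kff_duplicate_error")

  set.seed(44)
  for (i in 1:20) {
    k <- sample(6:21, 1) # keep 4^k well above the requested set size
    kmers <- random_kmers(sample(10:500, 1), k)
    spss <- greedy_compact(kmers, k)
    windows <- unlist(lapply(spss, kmers_of_sequence, k = k))
    expect_identical(sort(windows), sort(kmers)) # each input k-mer exactly once
    expect_lte(length(spss), length(kmers))
    expect_lte(sum(nchar(spss)), length(kmers) * k)
  }
})

test_that("greedy compaction recovers few strings from spectrum-like sets", {
  gen <- generate_spectrum_set(n_strings = 4, string_length = 300, k = 25,
                               noise_kmers = 0, seed = 5)
  expect_identical(anyDuplicated(gen$kmers$kmer), 0L)
  spss <- greedy_compact(gen$kmers$kmer)
  # at least the number of sources, at most set size; typically close to sources
  expect_gte(length(spss), length(gen$strings))
  expect_lt(length(spss), nrow(gen$kmers) / 10)
})

test_that("minimizer bucketing preserves the set and sets skeleton sizes", {
  toy_kmers <- c("ACTAAACTGA", "CTAAACTGAT", "TAAACTGATG")
  bk <- bucket_superkmers(toy_kmers, k = 10, m = 8)
  f <- kff_file(kff_header(unique_kmers = TRUE), c(
    list(kff_section_v(k = 10, max = bk$max, data_size = 0, m = 8)),
    bk$sections
  ))
  expect_identical(sort(kff_kmers(kff_parse(kff_serialize(f)))$kmer), sort(toy_kmers))

  single <- bucket_superkmers("ACTAAACTGA", k = 10, m = 8)
  expect_identical(length(single$sections), 1L)
  blk <- single$sections[[1]]$blocks[[1]]
  expect_identical(nchar(blk$skeleton), 10L - 8L) # k - m
})

test_that("compaction modes preserve the (k-mer, data) multiset", {
  set.seed(46)
  kmers <- random_kmers(400, 15)
  counts <- sample(1:9000, length(kmers), replace = TRUE)
  naive <- kff_from_text(sprintf("%s\t%d", kmers, counts), data_size = 2)

  for (mode in c("superkmer", "spss", "naive")) {
    out <- kff_compact(naive, mode = mode, m = 6)
    expect_same_stream(out, naive)
    rt <- kff_parse(kff_serialize(out))
    expect_same_stream(rt, naive)
    expect_identical(kff_validate(rt)$status, 0L)
  }

  # per-k-mer counts still attached to the right k-mer after re-layout
  sk <- kff_kmers(kff_compact(naive, mode = "superkmer", m = 6))
  expect_identical(sk$count[match(kmers, sk$kmer)], as.numeric(counts))
})

test_that("block bounds are honoured when max forces splitting", {
  set.seed(47)
  gen <- generate_spectrum_set(2, 200, 11, seed = 8)
  naive <- kff_from_text(gen$kmers$kmer)
  sk <- kff_compact(naive, mode = "superkmer", m = 5, max = 3)
  for (s in sk$sections) {
    if (s$type != "m") next
    for (b in s$blocks) expect_lte(nchar(b$skeleton) - 11 + 1 + 5, 3)
  }
  expect_same_stream(sk, naive)
  spss <- kff_compact(naive, mode = "spss", max = 4)
  expect_same_stream(spss, naive)
  expect_identical(kff_validate(kff_parse(kff_serialize(spss)))$status, 0L)
})

test_that("duplicate k-mers are rejected by set compaction but kept by naive", {
  dup <- kff_from_text(c("ACGT", "ACGT"))
  expect_error(kff_compact(dup, mode = "superkmer", m = 2),
               class = "kff_duplicate_error")
  expect_error(kff_compact(dup, mode = "spss"), class = "kff_duplicate_error")
  expect_identical(nrow(kff_kmers(kff_compact(dup, mode = "naive"))), 2L)
})

test_that("uncompaction is the stream-preserving inverse", {
  toy <- kff_toy_file()
  # drop the R section: uncompact the pure-M representation
  monly <- kff_file(toy$header, toy$sections[c(1, 3)])
  un <- kff_uncompact(monly)
  types <- vapply(un$sections, function(s) s$type, character(1))
  expect_identical(types, c("v", "r"))
  expect_identical(length(un$sections[[2]]$blocks), 3L)
  expect_identical(un$sections[[1]]$vars[["max"]], 1)
  expect_same_stream(un, monly)
  expect_same_stream(kff_uncompact(un), un) # idempotent on content
})
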