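test_that("validate distinguishes clean, violating and unparseable files", {
  dir <- withr::local_tempdir()
  toy <- file.path(dir, "toy.kff")
  kff_write(kff_toy_file(), toy)
  expect_identical(kff_validate(toy)$status, 0L)

  # corrupt end magic: warning, still status 0
  b <- as.vector(kff_serialize(kff_toy_file()))
  chopped <- b[1:(length(b) - 3)]
  res <- kff_validate(chopped)
  expect_identical(res$status, 0L)
  expect_match(res$warnings, "end-magic")

  # tamper the stored n of the R block (offset computed from the layout)
  off <- attr(kff_serialize(kff_toy_file()), "section_offsets")
  rpos <- off$start[off$type == "r"] + 1 + 4 + 1 # into the n byte
  bad <- b
  bad[rpos] <- as.raw(200)
  resb <- kff_validate(bad)
  expect_identical(resb$status, 3L) # truncation: 200 k-mers don't fit the bytes

  expect_identical(kff_validate(charToRaw("not kff"))$status, 3L)
  expect_identical(kff_validate(file.path(dir, "absent.kff"))$status, 3L)
})

test_that("instr reports counts, sizes and bits per k-mer", {
  set.seed(51)
  kmers <- random_kmers(100, 32)
  f <- kff_from_text(kmers)
  b <- kff_serialize(f)
  s <- kff_instr(b)
  expect_identical(s$kmer_count, 100L)
  expect_identical(s$section_counts[["r"]], 1)
  expect_identical(s$file_bytes, length(b))
  # header 15 + V section 49 + R head 5, then one 32-mer per block at
  # max=1: exactly 8 sequence bytes per k-mer
  expect_identical(s$file_bytes, 15L + 49L + 5L + 100L * 8L)
  expect_identical(s$bits_per_kmer, 8 * length(b) / 100)

  withcounts <- kff_instr(kff_from_text(sprintf("%s\t%d", kmers, seq_along(kmers)),
                                        data_size = 2))
  expect_identical(withcounts$data_bytes, 200L)
  expect_identical(withcounts$bits_per_kmer - withcounts$bits_per_kmer_no_data, 16)

  empty <- kff_instr(kff_file())
  expect_identical(empty$kmer_count, 0L)
  expect_true(is.na(empty$bits_per_kmer))
})

test_that("text dumps convert to KFF and back, preserving counts", {
  lines <- c("ACTAAACTGA\t1", "CTAAACTGAT\t2", "TAAACTGATG\t1")
  f <- kff_from_text(lines, data_size = 1)
  expect_identical(sort(kff_to_text(f)), sort(lines))

  expect_identical(length(kff_from_text(character(0))$sections), 0L)
  expect_error(kff_from_text(c("ACGT", "ACG")), class = "kff_length_error")
  expect_error(kff_from_text("ACGT\t300", data_size = 1), class = "kff_overflow_error")
  expect_error(kff_from_text("ACGT", data_size = 1), class = "kff_usage_error")
  expect_error(kff_from_text(c("ACGT", "ACGT"), unique = TRUE),
               class = "kff_duplicate_error")

  set.seed(52)
  big <- sprintf("%s\t%d", random_kmers(2000, 21), sample(1:65000, 2000, replace = TRUE))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "dump.kff")
  kff_from_text(big, path, data_size = 2)
  expect_identical(sort(kff_to_text(path)), sort(big))
})

test_that("gzip-compressed text dumps are read transparently", {
  dir <- withr::local_tempdir()
  gz <- file.path(dir, "kmers.tsv.gz")
  con <- gzfile(gz, "w")
  writeLines(c("ACGTACGT\t3", "TTTTACGT\t1"), con)
  close(con)
  f <- kff_from_text(gz, data_size = 1)
  expect_identical(sort(kff_kmers(f)$kmer), c("ACGTACGT", "TTTTACGT"))
})

test_that("merge concatenates compatible sets and re-verifies uniqueness", {
  set.seed(53)
  a_kmers <- random_kmers(10, 9)
  b_kmers <- setdiff(random_kmers(15, 9), a_kmers)
  fa <- kff_from_text(a_kmers, unique = TRUE)
  fb <- kff_from_text(b_kmers, unique = TRUE, encoding = kff_encoding(3, 2, 1, 0))
  merged <- kff_merge(list(fa, fb))
  expect_identical(nrow(kff_kmers(merged)), length(a_kmers) + length(b_kmers))
  expect_true(merged$header$unique_kmers)
  # encodings differ between inputs; output re-encodes to the first input's
  expect_identical(merged$header$encoding, fa$header$encoding)
  expect_identical(sort(kff_kmers(kff_parse(kff_serialize(merged)))$kmer),
                   sort(c(a_kmers, b_kmers)))

  # overlap clears the uniqueness flag
  overlap <- kff_merge(list(fa, fa))
  expect_false(overlap$header$unique_kmers)
  expect_identical(nrow(kff_kmers(overlap)), 2L * length(a_kmers))

  # empty file is the identity element
  expect_same_stream(kff_merge(list(fa, kff_file())), fa)

  fc <- kff_from_text(random_kmers(5, 12))
  expect_error(kff_merge(list(fa, fc)), class = "kff_compat_error")
})

test_that("split emits one self-contained file per sequence section", {
  dir <- withr::local_tempdir()
  paths <- kff_split(kff_toy_file(), file.path(dir, "part"))
  expect_identical(length(paths), 2L) # 1 R + 1 M section
  for (p in paths) expect_identical(kff_validate(p)$status, 0L)
  back <- kff_merge(as.list(paths))
  expect_same_stream(back, kff_toy_file())

  single <- kff_from_text(c("ACGT", "AAAA"))
  sp <- kff_split(single, file.path(dir, "single"))
  expect_identical(length(sp), 1L)
  expect_same_stream(sp[1], single)
})

test_that("the CLI dispatches commands with the documented exit statuses", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "in.tsv")
  writeLines(c("ACTAAACTGA\t1", "CTAAACTGAT\t2", "TAAACTGATG\t1"), tsv)
  out <- file.path(dir, "out.kff")

  expect_identical(kff_cli(c("from-text", tsv, "-o", out, "--data-size", "1")), 0L)
  expect_identical(kff_cli(c("validate", out)), 0L)

  sk <- file.path(dir, "sk.kff")
  expect_identical(kff_cli(c("compact", out, "-o", sk, "--mode", "superkmer", "-m", "8")), 0L)
  expect_same_stream(sk, out)

  un <- file.path(dir, "un.kff")
  expect_identical(kff_cli(c("uncompact", sk, "-o", un)), 0L)
  expect_same_stream(un, out)

  ix <- file.path(dir, "ix.kff")
  expect_identical(kff_cli(c("index", out, "-o", ix)), 0L)
  expect_identical(kff_cli(c("validate", ix)), 0L)

  txt <- file.path(dir, "back.tsv")
  expect_identical(kff_cli(c("to-text", un, "-o", txt)), 0L)
  expect_identical(sort(readLines(txt)), sort(readLines(tsv)))

  expect_output(expect_identical(kff_cli(c("instr", out, "--json")), 0L),
                '"kmer_count": 3')

  # statuses: usage 2, parse/io 3, structural violations 1
  expect_identical(suppressMessages(kff_cli(c("compact", out))), 2L)
  expect_identical(suppressMessages(kff_cli("frobnicate")), 2L)
  expect_identical(suppressMessages(kff_cli(c("validate", file.path(dir, "no.kff")))), 3L)
  bad <- file.path(dir, "bad.kff")
  writeLines("this is not kff", bad)
  expect_identical(kff_cli(c("validate", bad)), 3L)
  viol <- file.path(dir, "viol.kff")
  kff_write(kff_file(kff_header(unique_kmers = TRUE), list(
    kff_section_v(k = 4, max = 255, data_size = 0),
    kff_section_r(kff_block("AAAAA"))
  )), viol)
  expect_output(expect_identical(kff_cli(c("validate", viol)), 1L), "duplicate k-mer")

  enc <- file.path(dir, "enc.kff")
  expect_identical(kff_cli(c("from-text", tsv, "-o", enc, "--data-size", "1",
                             "--encoding", "GTCA")), 0L)
  expect_same_stream(enc, out)
  expect_identical(suppressMessages(
    kff_cli(c("from-text", tsv, "-o", enc, "--encoding", "GGCA"))), 2L)
})
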