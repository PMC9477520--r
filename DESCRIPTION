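Package: kffr
Title: Read, Write and Manipulate K-mer File Format (KFF) Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A codec and manipulation toolkit for the K-mer File Format
    (KFF), a sectioned binary container for k-mer sets with per-k-mer data
    payloads. Provides bit-exact reading and writing of the format's
    header and V/R/M/I sections, a streaming k-mer iterator that works on
    any section mix, conversion from and to plain-text k-mer dumps, and
    space-efficient compaction of flat k-mer sets into minimizer-bucketed
    super-k-mer sections or greedy spectrum-preserving string sets.
    Includes a deterministic generator of spectrum-like synthetic k-mer
    sets for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
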