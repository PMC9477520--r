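---
title: "The KFF dialect, minimizers and compaction in kffr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The KFF dialect, minimizers and compaction in kffr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kffr)
```

## Why a k-mer file format

Many sequence-analysis tools are *consumers* of k-mer sets produced by
k-mer counters: assemblers, aligner indexes, large-scale search tools. The
producers have historically written ad hoc binary dumps, so every consumer
needs a parser per producer. KFF is a sectioned binary container for k-mer
sets with fixed-width per-k-mer data (typically abundances) that any tool
can read sequentially. Two properties drive the design:

* **2-bit packing.** Over {A,C,G,T} a nucleotide needs 2 bits; a k-mer
  needs `ceiling(k/4)` bytes.
* **The spectrum-like property.** Most k-mers of a sequencing dataset
  arise as windows of a few long underlying strings. Storing overlapping
  k-mers as longer sequences (n k-mers in n + k - 1 nucleotides instead
  of n * k) is where the large space savings come from.

The trade-off is deliberate: KFF supports sequential streaming only. There
is no random access by k-mer, and the index (I) section indexes *section
positions*, never k-mers.

## The file model

A file is a 12-byte-plus-metadata header followed by sections:

* **V** sections define named unsigned variables. `k`, `max` (the bound on
  k-mers per block) and `data_size` (bytes of payload per k-mer) must be
  defined before the first sequence section, `m` (minimizer size) before
  the first M section. Later definitions override earlier ones, so one
  file can hold several k values.
* **R** sections store blocks of `n` overlapping k-mers as an explicit
  sequence of `n + k - 1` nucleotides plus `n * data_size` payload bytes.
* **M** sections factor out a shared minimizer: the section stores the
  m-mer once, and each block stores only the *skeleton* (the super-k-mer
  with the m-mer deleted) plus the 0-based position at which to re-insert
  it. For the toy example with `k = 10`, `m = 8`, the skeleton `ACTG` with
  minimizer `AAACTGAT` at position 3 reconstructs to the 12-nucleotide
  `ACTAAACTGATG`, carrying three 10-mers:

```{r}
reconstruct_sequence("ACTG", "AAACTGAT", 3)
kmers_of_sequence(reconstruct_sequence("ACTG", "AAACTGAT", 3), 10)
```

* **I** sections list `(section type, signed byte offset)` pairs relative
  to the first byte after the index, with a trailing offset chaining to
  the next index (0 = none). `kff_build_index()` appends a terminal index
  over all sections.

## Dialect decisions

The byte-level layout of this package is normative for files it writes and
is versioned 1.0; byte-for-byte compatibility with other KFF
implementations is not asserted. The choices, and why:

* **Big-endian everywhere** (network order, platform independent).
* **Right-aligned packing**: nucleotides go 4 per byte in order, the final
  nucleotide in the two least significant bits of the last byte, padding
  zeroed in the most significant bits of the *first* byte. Under an
  order-preserving encoding, numeric comparison of equal-length packed
  k-mers then equals lexicographic comparison.
* **Encoding byte** packs the codes of A, C, G, T from most to least
  significant bit pair (the default A:0 C:1 G:3 T:2 gives `0x1e`).
* **Field widths are derived, not stored.** A block's `n` takes
  `ceiling(bitlength(max)/8)` bytes and is omitted entirely when
  `max = 1`; the minimizer position takes
  `ceiling(bitlength(max + k - 1 - m)/8)` bytes. `bitlength` is the true
  bit length of the value (`floor(log2 v) + 1`), so the largest legal
  value always fits — e.g. with `max = 255`, `k = 10`, `m = 8` the bound
  256 needs 9 bits, hence a 2-byte position field.
* **End-magic leniency**: a missing trailing `KFF` is a validation
  warning, not a read error, so deliberately truncated streams and pipes
  still parse.
* **Unknown section types abort parsing.** Sections carry no length field,
  so there is nothing safe to skip by.
* **Canonical order is defined on letters (A\<C\<G\<T), never on the
  file's numeric encoding.** Canonicity is a property of the k-mer set and
  must survive re-encoding. Files produced under an encoding-relative
  convention by other tools would need their canonical flag cleared on
  import.
* Compression is layered outside the format (gzip the whole file), never
  inside sections.

## Minimizers, super-k-mers and the greedy SPSS

`minimizer_of()` returns the lexicographically smallest length-m window
(letter order, leftmost on ties). `split_into_superkmers()` computes each
k-window's minimizer and cuts the run wherever the minimizer *occurrence*
(position, not just sequence) changes; each maximal run is a super-k-mer.

```{r}
minimizer_of("ACTAAACTGATG", 8)
str(split_into_superkmers("ACTAAACTGATG", k = 10, m = 8))
```

Note that strict per-window splitting yields two super-k-mers here, while
the toy M section stores all three k-mers in a single block. The M-block
contract in this package is deliberately the weaker one — the block's
reconstructed sequence contains the section m-mer at the stated position —
so both producers are legal; strictness is a producer choice, and
`bucket_superkmers()` produces strict super-k-mers.

`greedy_compact()` builds a spectrum-preserving string set (SPSS): a set
of strings whose k-windows are exactly the input k-mers, each represented
once. It is a greedy path cover of the (k-1)-overlap graph: seed with the
first unused k-mer in input order, extend right then left, trying
extensions in A\<C\<G\<T order. This is *not* a minimum SPSS — optimal
constructions exist as separate tools and are out of scope here — but it
is deterministic, linear-time, and recovers long source strings from
spectrum-like sets almost exactly. Because it is defined on sets,
duplicate k-mers are an error in `superkmer`/`spss` modes, and the
resulting files set the unique-k-mers header flag; the naive layout
accepts duplicates.

Data payloads stay aligned through every re-layout: window i of a block
carries payload i, and payload bytes are opaque to the codec (the text
converter reads/writes them as big-endian counts).

## Parameters that matter

| parameter   | meaning                              | default | notes |
|-------------|--------------------------------------|---------|-------|
| `k`         | k-mer size (nt)                      | from input | any value 1..; tested 2–64 |
| `m`         | minimizer size (nt), `m <= k`        | 10      | smaller m means fewer, larger buckets |
| `max`       | k-mer bound per block                | smallest that avoids splitting | controls the width of the `n` field |
| `data_size` | payload bytes per k-mer              | 0       | counts decode as big-endian |
| encoding    | 2-bit code permutation               | A:0 C:1 G:3 T:2 | any permutation of 0..3 |

`m = 10` mirrors common practice for 32-mer workloads: buckets stay small
enough to keep per-section overhead negligible while skeletons drop 10 of
every super-k-mer's nucleotides.

## What the synthetic generator does and does not emulate

`generate_spectrum_set()` draws uniform random source strings, takes their
k-windows with multiplicities as counts, and adds isolated uniform random
noise k-mers (noise may collide with genuine k-mers; counts then merge,
as error k-mers do in real counters). It reproduces exactly the property
the overlap layouts exploit — most k-mers lie on a few long strings — and
is fully reproducible from an integer seed (Mersenne-Twister, caller RNG
state restored).

It does **not** emulate genomic repeat structure, coverage-dependent count
distributions, strand sampling, or quality-driven error models. Passing
tests therefore demonstrate codec correctness and the *qualitative* space
ordering (naive > super-k-mer > SPSS layouts) on spectrum-like data; they
do not certify the absolute bits-per-k-mer a real read set would achieve,
which depends on its repeat content and error rate.

## Numerical and degenerate-input choices

* Integers ride in doubles internally; every field this dialect writes is
  exact below 2^53. 8-byte values beyond that are rejected rather than
  silently rounded. Signed index offsets are two's-complemented bytewise.
* Empty sequence, empty skeleton (a k-mer equal to its minimizer), empty
  metadata, empty index and header-only files are all legal and tested.
* Ties in the minimizer scan break to the leftmost occurrence; the
  incremental scan only replaces the current minimum on a *strictly*
  smaller trailing m-mer, which preserves that tie-break.
* Lower-case input is upper-cased; any non-ACGT symbol (including N) is an
  error naming the offending position. KFF has no ambiguity codes, so
  producers must pre-filter.

## Scales used by the test suite

The bundled suites run at sizes chosen to finish comfortably on one CPU
while still exercising every code path: 1000 randomized files for the
bit-exact round-trip property (random encodings, k in 2..64, m in 1..k,
data_size 0..4), 10^5 random instances for the minimizer-versus-
exhaustive-scan oracle, 500-k-mer sets for the greedy SPSS window-multiset
oracle, and a 10-string x 100 kb (k = 32, m = 10) spectrum fixture of
about one million k-mers for the storage-ordering check, where the
super-k-mer layout lands well under half the naive file size and the SPSS
layout under that.

## Known limitations

* No random access and no k-mer index: consumers stream.
* Interoperability with files from other KFF implementations is not
  guaranteed at the byte level (field widths and footer are dialect
  decisions); the text dump is the portable interchange path.
* The greedy SPSS is not minimal; counts above 2^53 lose exactness in the
  R-level decode; compaction holds the whole record set in memory, so
  multi-billion-k-mer sets are out of scope for this implementation.
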