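# kffr — read, write and manipulate K-mer File Format (KFF) files

Bioinformatics tools increasingly exchange *k*-mer sets on disk: k-mer
counters produce them, and assemblers, aligner indexes and search tools
consume them. KFF is a sectioned binary container for k-mer sets with
fixed-width per-k-mer data (typically abundance counts) designed for that
exchange. `kffr` is a complete R codec and manipulation toolkit for the
format: bit-exact reading/writing, a streaming k-mer iterator, conversion
from/to plain-text counter dumps, and compaction of flat k-mer sets into
space-efficient overlapping layouts. It is aimed at R users who need to
inspect, validate, transform or synthesize k-mer set files without leaving
the language, and at pipelines that want a scriptable `kff` command.

## The ideas in the format

A nucleotide over {A,C,G,T} takes 2 bits, so a k-mer takes ⌈k/4⌉ bytes.
Beyond that, KFF exploits the *spectrum-like property* — most k-mers of a
dataset occur as consecutive windows of a few long strings — by storing
*n* overlapping k-mers as one sequence of *n* + *k* − 1 nucleotides:

* **R sections** store such sequences explicitly.
* **M sections** go further using **minimizers** (the lexicographically
  smallest *m*-window of a sequence, leftmost on ties). A **super-k-mer**
  is a maximal run of consecutive k-mers sharing one minimizer occurrence;
  all super-k-mers with the same minimizer go in one section, which stores
  the m-mer once while each block keeps only the *skeleton* (the sequence
  with the m-mer deleted) plus its re-insertion position.
* **V sections** define the running variables (`k`, `max`, `data_size`,
  `m`); **I sections** index section positions (never k-mers — KFF is a
  purely sequential format).

For turning a flat set into overlapping form, `greedy_compact()` builds a
**spectrum-preserving string set** (SPSS): a greedy path cover of the
(k−1)-overlap graph whose strings' k-windows are exactly the input set,
each represented once.

## Worked example

Three 10-mers with counts, as a counter would dump them:

```r
library(kffr)
f <- kff_from_text(c("ACTAAACTGA\t1", "CTAAACTGAT\t2", "TAAACTGATG\t1"),
                   data_size = 1)
kff_kmers(f)
#>         kmer count data
#> 1 ACTAAACTGA     1   01
#> 2 CTAAACTGAT     2   02
#> 3 TAAACTGATG     1   01
```

These three k-mers are the windows of `ACTAAACTGATG`, whose 8-mer
minimizer sits at 0-based position 3:

```r
minimizer_of("ACTAAACTGATG", 8)
#> $minimizer
#> [1] "AAACTGAT"
#> $position
#> [1] 3
reconstruct_sequence("ACTG", "AAACTGAT", 3)  # skeleton + minimizer back
#> [1] "ACTAAACTGATG"
```

Re-laying the file out as minimizer sections keeps the stream identical:

```r
sk <- kff_compact(f, mode = "superkmer", m = 8)
kff_to_text(sk)
#> [1] "ACTAAACTGA\t1" "CTAAACTGAT\t2" "TAAACTGATG\t1"
```

On toy input the per-section overhead dominates; on spectrum-like data the
overlap layouts win decisively. Ten random 10 kb strings give 99 690
distinct 32-mers, and the three layouts produced by `kff_compact()` land
at (as printed by the code in `vignettes/kff-format.Rmd`, seed 1):

```
naive     797 589 B   64.0 bits/k-mer
superkmer 166 805 B   13.4 bits/k-mer
spss       25 089 B    2.0 bits/k-mer
```

`kff_validate()`, `kff_instr()`, `kff_merge()`, `kff_split()`,
`kff_index()` and `kff_uncompact()` round out the toolkit; the same verbs
are available from the shell via the `kff` script (`kff --help`).

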