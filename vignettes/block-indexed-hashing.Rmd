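---
title: "Block-indexed rolling hashing of spaced seeds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block-indexed rolling hashing of spaced seeds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedhash)
```

## The problem

A *spaced seed* is a binary pattern such as `1101110011111` in which `1`
demands a symbol match and `0` is a don't-care. Compared with contiguous
k-mers, spaced seeds sample positions that are statistically less dependent,
which is why they underpin many sensitive sequence-comparison methods
(read classification, alignment seeding, alignment-free distances). The
price is computational: a contiguous k-mer hash can be rolled along a
sequence in constant time per position because adjacent windows share
`k - 1` symbols, but the don't-cares of a spaced seed break that overlap,
so the textbook approach re-reads and re-encodes all `W` matched symbols at
every position.

`seedhash` removes most of that cost by *block indexing*. Every seed is a
series of unit blocks — maximal runs of 1s — separated by runs of 0s.
Each block of length `l` intercepts a plain l-mer, and l-mer hashes *can*
be rolled. So the package:

1. decomposes the seed into blocks with 0-based starts `B` and lengths
   `B_L` (`decompose_blocks()`);
2. builds, per distinct block length `l`, a table `T_l` holding the rolling
   hash of every contiguous l-mer of the sequence
   (`build_kmer_table()`);
3. assembles the seed hash at position `i` as the bitwise OR over blocks
   `j` of `T_{l_j}[i + b_j] << 2·m(b_j)`, where `m(k)` counts the 1s
   strictly left of offset `k` (`fish_hash_stream()`).

Each input symbol is then touched once per *block length* instead of once
per *match position*, and with several seeds the tables are shared: only
one table per distinct block length across the whole seed set is ever
built (`plan_multi()`, `fish_multi_hash_stream()`).

## The hash function

Nucleotides are encoded in 2 bits (`A=00, C=01, G=10, T=11`; `U` is read
as `T`, case-insensitively). For a seed with shape `Q` (the 0-based offsets
of its 1s) the hash of the Q-gram at position `i` is

    h(x[i+Q]) = OR over k in Q of ( encode(x[i+k]) << 2·m(k) )

i.e. a Rabin-Karp-style radix-4 codeword of the matched symbols with the
*first* matched symbol in the least-significant bits. The binary rendering
used throughout (`hash_bits()`) is the plain big-endian binary string of
that integer zero-padded to `2W` bits, which lists the last matched
symbol's code leftmost:

```{r}
s <- parse_seed("1101110011111")
qgram("ACTGACTGGATTGAC", s, 0)
hash_bits(fish_hash_stream("ACTGACTGGATTGAC", s))
```

`naive_hash_stream()` evaluates the definition directly at every position
and is deliberately kept as an independent execution path: it is the
correctness oracle that the block-indexed path is tested against, and the
baseline the benchmark harness times against.

### Numerical representation

Hash values occupy `2W` bits. R has no 64-bit unsigned integer type and
its doubles are exact only to 2^53, so all hash arithmetic lives in
compiled code (`uint64_t`) and values cross the R boundary as decimal
strings. That choice makes equality checks, TSV output and set operations
trivial and exact; it caps the supported weight at `W <= 32`, which
`parse_seed()` enforces with a clear error. The benchmark seed sets in
common use have `W <= 32`, and heavier seeds would need multi-word hashes,
an explicit non-goal.

Two edge conventions:

* **Degenerate seeds.** All-1 patterns (no don't-cares) are accepted even
  though the strict definition requires at least one 0; block indexing
  then reduces to a single k-mer table lookup, which is a useful
  boundary case for testing and costs nothing to support.
* **Ambiguous bases.** `N` and any other non-ACGT symbol get code 0 plus a
  `FALSE` validity flag. Validity propagates: a stream position is valid
  iff all `W` matched symbols are valid. Invalid positions keep their
  (well-defined) computed hash and carry the flag — downstream consumers
  decide whether to skip them. Real FASTQ contains Ns, and flagging is
  lossless where skipping would not be.

## The cyclic-polynomial variant

The same block decomposition carries over to a cyclic-polynomial (buzhash
style) rolling hash, useful when better hash-value distribution is wanted:
each base is assigned a random 64-bit word (`make_salt_table()`, derived
from an integer seed with a splitmix64 generator so the table is
platform-independent), shifts become bit rotations and OR becomes XOR.
Rotations compose additively mod 64, so rotating a block's table value by
`m(b_j) mod 64` and XOR-ing reproduces the per-position definition
exactly; `cyclic_hash_stream()` implements both routes and the test suite
checks their elementwise agreement.

## The read simulator

`simulate_reads()` generates i.i.d. random reads: bases drawn with
`P(G) = P(C) = gc/2`, `P(A) = P(T) = (1-gc)/2` (default `gc = 0.5`), each
base independently replaced by `N` with probability `n_rate` (default 0).
It emulates what matters for hashing — read length, composition,
ambiguous bases — and deliberately nothing else: substitution sequencing
errors produce just another base, indistinguishable to a hash function,
so an error profile would not exercise any additional code path.
Consequently, passing tests on simulated reads demonstrate hashing
correctness on arbitrary DNA, but say nothing about downstream,
application-level properties (classification accuracy, seed sensitivity),
which are out of scope. Reads are reproducible byte-for-byte from
`rng_seed` via R's Mersenne-Twister stream, which behaves identically
across platforms. Read lengths of interest in the tests span 80-700 bp,
the range typical of short-read and 454-style datasets; the bundled
nine-seed benchmark set (`table2_seeds()`, weight 22, span 31) covers the
three usual seed-design criteria.

## Benchmarking philosophy

`benchmark_hashing()` times three routes — naive, block-indexed, and
block-indexed with shared tables — on identical inputs, reporting medians
over repetitions. Before any clock starts it verifies all outputs bitwise
identical and aborts otherwise: a mismatch is a correctness bug, never a
timing footnote. Speedup figures are *informational only*; they depend on
hardware, compiler and read-length mix, so no test asserts a numeric
speedup. The structural property worth asserting, and asserted, is table
sharing: the multi-seed route builds exactly one table per distinct block
length in the union across seeds, never more than the per-seed total.
The block-indexed advantage grows with read length (the per-read table
set-up transient amortizes) and with seed density `W/L`; for sparse seeds
(density below roughly 0.3) the naive route can win, which is expected
behavior, not a defect.

## Problem sizes in the tests

The property-based suites run on deliberately moderate sizes chosen to
exercise every code path many times over: the oracle-equivalence
acceptance check covers 1000 random read/seed pairs with read lengths
80-700 and seed spans up to 45 at densities 0.3-1.0; rolling-table checks
cross-validate all `l` in 1..16 against an arithmetic recomputation (exact
in doubles up to 26 matched symbols, which bounds the pure-R oracles);
multi-seed consistency runs the full nine-seed set over 50 simulated
reads. Degenerate inputs — empty sequences, reads shorter than the span,
`l = n` windows, all-1 and single-`1` seeds, zero-length FASTQ records —
are covered explicitly.

## Known limitations

* Weight is capped at 32 (single 64-bit word per hash).
* Hashing is strand-specific; canonical (strand-symmetric) hashing,
  minimizers, and downstream counting/indexing are out of scope.
* FASTQ parsing expects the 4-line record layout (universal for NGS
  reads); wrapped FASTQ is rejected with a record-indexed error.
* Paired-end reads are hashed as independent records.
* Seed *design* (sensitivity optimization) is a non-goal; seeds are
  inputs.
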