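Package: seedhash
Title: Block-Indexed Rolling Hashing of Spaced Seeds on DNA Sequences
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the Rabin-Karp-style hash of every Q-gram intercepted
    by one or more spaced seeds along DNA sequences. A spaced seed is
    decomposed into its unit blocks (maximal runs of match positions); per
    block length a rolling k-mer hash table is built in a single pass, and
    the spaced-seed hash at each position is assembled by shifting and
    OR-ing the block hashes looked up in those tables. Multiple seeds share
    tables for common block lengths. A naive per-position implementation
    serves as the correctness oracle, and an optional cyclic-polynomial
    (rotate/XOR) hash variant is provided. Includes FASTA/FASTQ input,
    TSV/binary output, a reproducible read simulator, a benchmark harness,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
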