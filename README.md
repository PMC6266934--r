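# seedhash

Fast hashing of **spaced seeds** over DNA sequences by **block indexing**,
with a naive per-position implementation as the built-in correctness
oracle.

## The problem

A spaced seed is a binary pattern (e.g. `1101110011111`) where `1` requires
a symbol match and `0` is a don't-care; it begins and ends with `1`. Its
*shape* `Q` is the 0-based offset set of the 1s, its *weight* `W = |Q|`,
its *span* `s(Q) = max(Q) + 1`. Spaced seeds give more sensitive sequence
comparison than contiguous k-mers, but hashing them is slow: the Q-gram
hash

```
h(x[i+Q]) = OR_{k in Q} ( encode(x[i+k]) << 2·m(k) )
```

(`encode`: A=00, C=01, G=10, T=11; `m(k)` = number of 1s left of `k`)
cannot be rolled from position `i` to `i+1` the way a k-mer hash can, so
the textbook route re-encodes all `W` matched symbols at every position.
Tools that adopt spaced seeds (read classifiers, aligners, alignment-free
methods) pay for their sensitivity with exactly this slowdown.

`seedhash` decomposes the seed into its **unit blocks** — maximal runs of
1s, starts `B`, lengths `B_L` — builds one rolling l-mer hash table `T_l`
per distinct block length (constant time per position, thanks to the
`l-1`-symbol overlap of consecutive l-mers), and assembles each Q-gram
hash as

```
h(i) = OR_j ( T_{l_j}[i + b_j] << 2·m(b_j) )
```

With multiple seeds the tables are shared across seeds: one table per
distinct block length in the whole set. The package is aimed at
bioinformaticians building seed-based indexes or classifiers who need the
full per-position hash stream of one or many seeds over read sets.

## Worked example

```r
library(seedhash)

s <- parse_seed("1101110011111")
s
#> <spaced_seed 1101110011111  W=10 span=13>

decompose_blocks(s)
#> <block_decomposition of 1101110011111>
#>   starts : {0,3,8}
#>   lengths: {2,3,5}

x <- "ACTGACTGGATTGAC"
sapply(0:2, function(i) qgram(x, s, i))
#> [1] "ACGACGATTG" "CTACTATTGA" "TGCTGTTGAC"

st <- fish_hash_stream(x, s)   # block-indexed; == naive_hash_stream(x, s)
st
#> <hash_stream: seed 1101110011111, 3 position(s), 20-bit hashes>
#>   [0] 772388
#>   [1] 193357
#>   [2] 311003

hash_bits(st)
#> [1] "10111100100100100100" "00101111001101001101" "01001011111011011011"
```

The three stream values are the radix-4 codewords of the three Q-grams:
`772388` is `10111100100100100100` in binary — the 2-bit codes of
`ACGACGATTG` with the first matched symbol in the least-significant bits.
`fish_hash_stream()` obtains it as
`(0100 << 0) | (010010 << 4) | (1011110010 << 10)`, looking the three
block hashes up in the rolling tables `T_2`, `T_3`, `T_5`;
`naive_hash_stream()` recomputes it symbol by symbol. The two agree
bitwise everywhere, and the test suite holds them to that.

Multiple seeds share tables (the bundled `table2_seeds()` set has
weight 22 and span 31, nine seeds, seven distinct block lengths):

```r
plan <- plan_multi(table2_seeds())
plan
#> <multi_seed_plan: 9 seed(s), shared table lengths {1,2,3,4,5,6,9}>
streams <- fish_multi_hash_stream(x_long, plan)  # 7 tables, not 21
```

## Command line

A thin wrapper is installed as `exec/seedhash`:

```sh
seedhash hash -i reads.fq -s 1101110011111 -o hashes.tsv   # or --method naive
seedhash multihash -i reads.fq -S seeds.txt -o hashes.tsv
seedhash simulate -n 1000 -l 200 --rng-seed 7 -o reads.fq --format fastq
seedhash bench -n 500 -l 400 -S seeds.txt --reps 3
```

TSV output columns: `record_id, seed_index, pos (0-based), hash (unsigned
decimal), valid (1/0)`; `--mode binary` writes a compact self-describing
container restored bit-exactly by `read_hash_stream()`. Positions whose
window touches a non-ACGT base keep their hash and carry `valid = 0`.
`bench` verifies all routes bitwise identical before timing them; its
speedup numbers are informational (hardware-dependent), while table
sharing is a hard guarantee.

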