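test_that("encode_sequence maps A/C/G/T to 2-bit codes and flags the rest", {
  enc <- encode_sequence("ACGT")
  expect_identical(enc$codes, c(0L, 1L, 2L, 3L))
  expect_true(all(enc$valid))
  # the 10-symbol example: A C G A C G A T T G
  enc2 <- encode_sequence("ACGACGATTG")
  expect_identical(enc2$codes, c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 3L, 3L, 2L))
  enc3 <- encode_sequence("ACNGT")
  expect_identical(enc3$valid, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_identical(enc3$codes[3], 0L)
  # normalization: case-insensitive, U treated as T
  expect_identical(encode_sequence("acgu")$codes, c(0L, 1L, 2L, 3L))
  expect_true(all(encode_sequence("acgu")$valid))
})

test_that("per-position hash reproduces the worked 20-bit codewords", {
  x <- "ACTGACTGGATTGAC"
  s <- parse_seed("1101110011111")
  h <- lapply(0:2, function(i) naive_qgram_hash(x, s, i))
  bits <- vapply(h, function(z) hash_bits(z$hash, 20), "")
  expect_identical(bits[1], "10111100100100100100")
  expect_identical(bits[2], "00101111001101001101")
  # third position, recomputed from the encoding layout (last matched
  # symbol is C, so the rendering must start with 01)
  expect_identical(bits[3], "01001011111011011011")
  expect_true(all(vapply(h, `[[`, TRUE, "valid")))
  # step-by-step prefix of 6 matched symbols: seed truncated after its
  # first six 1s, hashed over the first ten symbols
  pre <- naive_qgram_hash("ACTGACTGGA", "110111001", 0)
  expect_identical(hash_bits(pre$hash, 12), "100100100100")
  expect_error(naive_qgram_hash(x, s, 3), "out of range")
  expect_error(naive_qgram_hash(x, s, -1), "out of range")
})

test_that("per-position hash equals an arithmetic recomputation", {
  set.seed(11)
  for (rep in 1:20) {
    p <- random_seed_pattern(sample(1:20, 1), runif(1, 0.3, 1),
                             max_weight = 13L)
    x <- random_dna(sample(20:60, 1))
    s <- parse_seed(p)
    st <- naive_hash_stream(x, s)
    for (i in seq_along(st$hashes) - 1L) {
      expect_identical(st$hashes[i + 1L], oracle_qgram_dec(x, p, i))
    }
  }
})

test_that("naive stream handles boundaries and the identity seed", {
  x <- "ACTGACTGGATTGAC"
  s <- parse_seed("1101110011111")
  expect_length(naive_hash_stream(x, s), 3L)
  # n == span - 1 gives an empty stream
  short <- naive_hash_stream(substr(x, 1, s$span - 1), s)
  expect_length(short, 0L)
  expect_identical(short$hashes, character(0))
  # seed "1" reduces to per-symbol encoding
  st <- naive_hash_stream("ACGT", "1")
  expect_identical(st$hashes, c("0", "1", "2", "3"))
})

test_that("k-mer tables reproduce the worked block hashes", {
  x <- "ACTGACTGGATTGACTCC"
  t5 <- build_kmer_table(x, 5)
  expect_length(t5$hashes, nchar(x) - 5 + 1)
  expect_identical(hash_bits(t5)[9], "1011110010")   # position 8
  expect_identical(hash_bits(build_kmer_table(x, 2))[1], "0100")
  expect_identical(hash_bits(build_kmer_table(x, 3))[4], "010010")
  # l = 1 is the per-symbol code table
  t1 <- build_kmer_table("ACGT", 1)
  expect_identical(t1$hashes, c("0", "1", "2", "3"))
  expect_error(build_kmer_table(x, 0), "positive")
  expect_error(build_kmer_table(x, nchar(x) + 1), "exceeds the sequence")
  expect_error(build_kmer_table(x, 33), "maximum")
})

test_that("rolling table values equal per-position recomputation", {
  set.seed(23)
  for (rep in 1:5) {
    x <- random_dna(200, n_rate = 0.03)
    chars <- strsplit(x, "", fixed = TRUE)[[1]]
    for (l in 1:16) {
      tab <- build_kmer_table(x, l)
      recomputed <- vapply(seq_along(tab$hashes) - 1L,
                           function(i) oracle_kmer_dec(x, i, l), "")
      expect_identical(tab$hashes, recomputed)
      window_ok <- vapply(seq_along(tab$hashes) - 1L, function(i)
        all(chars[(i + 1):(i + l)] %in% c("A", "C", "G", "T")), TRUE)
      expect_identical(tab$valid, window_ok)
    }
  }
})

test_that("block recombination reproduces the worked example", {
  x <- "ACTGACTGGATTGACTCC"
  s <- parse_seed("1101110011111")
  # (0100 << 0) OR (010010 << 4) OR (1011110010 << 10)
  fi <- fish_hash_stream(x, s)
  expect_identical(hash_bits(fi)[1], "10111100100100100100")
  expect_same_stream(fi, naive_hash_stream(x, s))
})

test_that("block-indexed stream is bitwise identical to the naive oracle", {
  set.seed(37)
  for (rep in 1:40) {
    span <- sample(1:45, 1)
    p <- random_seed_pattern(span, runif(1, 0.3, 1))
    x <- random_dna(sample(50:300, 1), n_rate = 0.02)
    s <- parse_seed(p)
    expect_same_stream(fish_hash_stream(x, s), naive_hash_stream(x, s))
  }
})

test_that("an all-1 seed's stream is the k-mer table verbatim", {
  set.seed(5)
  x <- random_dna(100)
  st <- fish_hash_stream(x, "11111")
  tab <- build_kmer_table(x, 5)
  expect_identical(st$hashes, tab$hashes)
  expect_identical(st$valid, tab$valid)
})

test_that("pre-built tables are validated and reused", {
  x <- encode_sequence(random_dna(80))
  s <- parse_seed("1101110011111")
  tabs <- lapply(c(2, 3, 5), function(l) build_kmer_table(x, l))
  names(tabs) <- c("2", "3", "5")
  expect_same_stream(fish_hash_stream(x, s, tabs), naive_hash_stream(x, s))
  expect_error(fish_hash_stream(x, s, tabs[c("2", "3")]),
               "no k-mer table supplied for block length")
  wrong <- lapply(c(2, 3, 5), function(l)
    build_kmer_table(encode_sequence(random_dna(60)), l))
  names(wrong) <- c("2", "3", "5")
  expect_error(fish_hash_stream(x, s, wrong), "does not match the sequence")
})

test_that("hash values fit the declared bit width", {
  set.seed(41)
  for (rep in 1:10) {
    p <- random_seed_pattern(sample(2:45, 1), runif(1, 0.3, 1))
    s <- parse_seed(p)
    x <- random_dna(80)
    st <- fish_hash_stream(x, s)
    # rendering at exactly 2W bits errors if any hash >= 2^(2W)
    expect_no_error(hash_bits(st))
    tab <- build_kmer_table(x, sample(1:16, 1))
    expect_no_error(hash_bits(tab))
  }
})

test_that("flipping a base to N invalidates exactly the covering windows", {
  set.seed(53)
  x <- random_dna(60)
  s <- parse_seed("1101110011111")
  pos <- 25L  # 0-based position to corrupt
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  chars[pos + 1L] <- "N"
  xn <- paste(chars, collapse = "")
  st <- fish_hash_stream(xn, s)
  affected <- vapply(seq_along(st$valid) - 1L,
                     function(i) (pos - i) %in% s$shape, TRUE)
  expect_identical(st$valid, !affected)
  expect_same_stream(st, naive_hash_stream(xn, s))
  # hashes at invalid positions are computed with code 0, not a sentinel
  expect_true(all(nchar(st$hashes) > 0))
})

test_that("multi-seed streams equal single-seed runs and share tables", {
  set.seed(67)
  seeds <- lapply(c("1101110011111", "110111", "10101", "1111"), parse_seed)
  plan <- plan_multi(seeds)
  x <- random_dna(150, n_rate = 0.01)
  streams <- fish_multi_hash_stream(x, plan)
  expect_identical(attr(streams, "tables_built"),
                   length(plan$union_lengths))
  for (i in seq_along(seeds))
    expect_same_stream(streams[[i]], fish_hash_stream(x, seeds[[i]]))
  # degenerate plan: a singleton list behaves like the single-seed path
  single <- fish_multi_hash_stream(x, list(seeds[[1]]))
  expect_same_stream(single[[1]], fish_hash_stream(x, seeds[[1]]))
})

test_that("the nine bundled seeds all match their naive oracles", {
  set.seed(79)
  seeds <- table2_seeds()
  x <- random_dna(120)
  streams <- fish_multi_hash_stream(x, plan_multi(seeds))
  for (i in seq_along(seeds))
    expect_same_stream(streams[[i]], naive_hash_stream(x, seeds[[i]]))
})

test_that("sequences shorter than some block lengths still hash correctly", {
  # one seed's span exceeds the input: empty stream, no table error
  seeds <- list(parse_seed("11111"), parse_seed("1000000001"))
  x <- "ACGTACG"  # n = 7 < span 10
  streams <- fish_multi_hash_stream(x, plan_multi(seeds))
  expect_length(streams[[1]], 3L)
  expect_length(streams[[2]], 0L)
  expect_same_stream(streams[[1]], naive_hash_stream(x, seeds[[1]]))
})
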