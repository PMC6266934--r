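# Independent pure-R oracles and random-input generators. The oracles
# recompute hashes arithmetically (sums of code * 4^position as doubles),
# which is exact up to 2^53, i.e. for up to 26 matched symbols — enough to
# cross-check the compiled kernels at small scale without sharing any code
# path with them.

.code_of <- c(A = 0, C = 1, G = 2, T = 3)

# decimal string of the 2-bit concatenation hash of the l-mer at 0-based
# position i (first symbol least significant); NA if l > 26
oracle_kmer_dec <- function(x, i, l) {
  stopifnot(l <= 26)
  chars <- strsplit(x, "", fixed = TRUE)[[1]][(i + 1):(i + l)]
  codes <- ifelse(chars %in% names(.code_of), .code_of[chars], 0)
  sprintf("%.0f", sum(codes * 4^(seq_len(l) - 1)))
}

# decimal string of the spaced-seed hash of the Q-gram at 0-based position i
oracle_qgram_dec <- function(x, pattern, i) {
  bits <- as.integer(strsplit(pattern, "", fixed = TRUE)[[1]] == "1")
  shape <- which(bits == 1L) - 1L
  stopifnot(length(shape) <= 26)
  m <- cumsum(c(0L, bits[-length(bits)]))[shape + 1L]
  chars <- strsplit(x, "", fixed = TRUE)[[1]][i + shape + 1L]
  codes <- ifelse(chars %in% names(.code_of), .code_of[chars], 0)
  sprintf("%.0f", sum(codes * 4^m))
}

# random valid seed pattern: 1s at both ends, interior Bernoulli(density);
# excess 1s beyond max_weight are flipped off at random interior positions
random_seed_pattern <- function(span, density, max_weight = 32L) {
  stopifnot(span >= 1)
  if (span == 1) return("1")
  bits <- c(1L, rbinom(span - 2L, 1L, density), 1L)
  excess <- sum(bits) - max_weight
  if (excess > 0) {
    interior_ones <- setdiff(which(bits == 1L), c(1L, span))
    bits[sample(interior_ones, excess)] <- 0L
  }
  paste(c("0", "1")[bits + 1L], collapse = "")
}

random_dna <- function(n, n_rate = 0) {
  b <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (n_rate > 0) b[runif(n) < n_rate] <- "N"
  paste(b, collapse = "")
}

# reconstruct a pattern string from a block decomposition
pattern_from_blocks <- function(starts, lengths) {
  span <- starts[length(starts)] + lengths[length(lengths)]
  bits <- rep(0L, span)
  for (j in seq_along(starts))
    bits[(starts[j] + 1):(starts[j] + lengths[j])] <- 1L
  paste(c("0", "1")[bits + 1L], collapse = "")
}

expect_same_stream <- function(a, b) {
  expect_identical(a$hashes, b$hashes)
  expect_identical(a$valid, b$valid)
}
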