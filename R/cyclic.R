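#' Salt table for the cyclic-polynomial hash variant
#'
#' The cyclic-polynomial (rotate/XOR) rolling hash replaces the 2-bit
#' concatenation scheme: each nucleotide is assigned a random 64-bit word,
#' shifts become bit rotations and OR becomes XOR. The four words are drawn
#' with a splitmix64 generator from `rng_seed`, so the table is reproducible
#' across platforms; the four entries are guaranteed distinct.
#'
#' @param rng_seed Integer seed for the salt generator.
#' @return A character vector of 4 decimal 64-bit values named A, C, G, T.
#' @export
make_salt_table <- function(rng_seed) {
  rng_seed <- as.integer(rng_seed)
  if (length(rng_seed) != 1L || is.na(rng_seed))
    stop("`rng_seed` must be a single integer")
  salt <- cpp_salt_table(rng_seed)
  names(salt) <- c("A", "C", "G", "T")
  salt
}

check_salt <- function(salt_table) {
  if (!is.character(salt_table) || length(salt_table) != 4L ||
      anyNA(salt_table) || !all(grepl("^[0-9]+$", salt_table)))
    stop("`salt_table` must be 4 decimal 64-bit values; see make_salt_table()")
  salt_table
}

#' Cyclic-polynomial spaced-seed hash stream
#'
#' Hashes every Q-gram with the rotate/XOR variant: the naive definition is
#' `XOR` over match offsets `k` of `rotl64(salt[x[i+k]], m(k) mod 64)`. The
#' block-indexed path builds one cyclic l-mer table per distinct block
#' length (rotation amount = within-window index, rolled in constant time)
#' and recombines blocks as `XOR` of `rotl64(T_l[i+b], m(b) mod 64)`; both
#' methods agree elementwise because rotations compose additively mod 64.
#'
#' @inheritParams fish_hash_stream
#' @param salt_table 4-entry salt from [make_salt_table()].
#' @param method `"fish"` (block-indexed, default) or `"naive"`.
#' @return A `hash_stream` with 64-bit values (`width = 64`).
#' @export
cyclic_hash_stream <- function(x, seed, salt_table,
                               method = c("fish", "naive")) {
  x <- as_encoded(x)
  seed <- as_seed(seed)
  salt_table <- check_salt(salt_table)
  method <- match.arg(method)
  if (x$length < seed$span)
    return(new_hash_stream(seed, character(0), logical(0), 64L))
  if (method == "naive") {
    rots <- seed$m[seed$shape + 1L] %% 64L
    r <- cpp_cyclic_naive(x$codes, x$valid, seed$shape, rots,
                          unname(salt_table), seed$span)
  } else {
    d <- decompose_blocks(seed)
    dist_len <- sort(unique(d$lengths))
    tabs <- lapply(dist_len, function(l)
      cpp_cyclic_kmer_table(x$codes, x$valid, l, unname(salt_table)))
    block_tab <- match(d$lengths, dist_len) - 1L
    rots <- seed$m[d$starts + 1L] %% 64L
    r <- cpp_cyclic_combine(lapply(tabs, `[[`, "hashes"),
                            lapply(tabs, `[[`, "valid"),
                            block_tab, d$starts, rots, seed$span, x$length)
  }
  new_hash_stream(seed, r$hashes, r$valid, 64L)
}
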