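#' Encode a DNA sequence into 2-bit codes
#'
#' Maps `A -> 00`, `C -> 01`, `G -> 10`, `T -> 11` (case-insensitive; `U` is
#' treated as `T`). Any other symbol — ambiguity codes such as `N`, gaps,
#' stray characters — receives code 0 and a `FALSE` validity flag; validity
#' propagates through every downstream hash so that windows touching such a
#' symbol are flagged rather than dropped or fatal.
#'
#' @param x A single sequence string.
#' @return An object of class `encoded_sequence` with fields `codes`
#'   (integer vector in 0..3), `valid` (parallel logical vector) and
#'   `length`.
#' @examples
#' enc <- encode_sequence("ACGT")
#' enc$codes  # 0 1 2 3
#' @export
encode_sequence <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("`x` must be a single string")
  r <- cpp_encode(x)
  structure(
    list(codes = r$codes, valid = r$valid, length = length(r$codes)),
    class = "encoded_sequence"
  )
}

#' @export
print.encoded_sequence <- function(x, ...) {
  cat(sprintf("<encoded_sequence of %d symbol(s), %d invalid>\n",
              x$length, sum(!x$valid)))
  invisible(x)
}

as_encoded <- function(x) {
  if (inherits(x, "encoded_sequence")) x else encode_sequence(x)
}

new_hash_stream <- function(seed, hashes, valid, width) {
  structure(
    list(seed = seed, hashes = hashes, valid = valid, width = width),
    class = "hash_stream"
  )
}

#' @export
print.hash_stream <- function(x, n = 6L, ...) {
  cat(sprintf("<hash_stream: seed %s, %d position(s), %d-bit hashes>\n",
              x$seed$pattern, length(x$hashes), x$width))
  if (length(x$hashes)) {
    k <- min(n, length(x$hashes))
    cat(sprintf("  [%d] %s%s\n", seq_len(k) - 1L, x$hashes[seq_len(k)],
                ifelse(x$valid[seq_len(k)], "", " (invalid)")), sep = "")
    if (length(x$hashes) > k) cat("  ...\n")
  }
  invisible(x)
}

#' @export
length.hash_stream <- function(x) length(x$hashes)

#' Spaced-seed hash of a single Q-gram (naive path)
#'
#' Computes `OR` over match offsets `k` of `code(x[i + k]) << 2 * m(k)`,
#' where `m(k)` counts the 1s strictly left of `k` — the first matched
#' symbol occupies the least-significant bits.
#'
#' @param x An `encoded_sequence` (or a sequence string).
#' @param seed A `spaced_seed` (or pattern string).
#' @param i 0-based position, `0 <= i <= n - span`.
#' @return A list with `hash` (decimal string of the 64-bit value) and
#'   `valid` (`TRUE` iff all matched symbols are A/C/G/T).
#' @examples
#' h <- naive_qgram_hash("ACTGACTGGATTGAC", "1101110011111", 0)
#' hash_bits(h$hash, 20)  # "10111100100100100100"
#' @export
naive_qgram_hash <- function(x, seed, i) {
  x <- as_encoded(x)
  seed <- as_seed(seed)
  if (i < 0 || i > x$length - seed$span)
    stop("position ", i, " out of range 0..", x$length - seed$span)
  idx <- (i + 1L):(i + seed$span)
  r <- cpp_naive_stream(x$codes[idx], x$valid[idx], seed$shape,
                        2L * seed$m[seed$shape + 1L], seed$span)
  list(hash = r$hashes[[1L]], valid = r$valid[[1L]])
}

#' Spaced-seed hash stream, computed naively per position
#'
#' Applies the per-position hash at every `i = 0 .. n - span`, reading and
#' encoding each matched symbol anew — the reference implementation that the
#' block-indexed path is verified against. Inputs shorter than the span
#' yield an empty stream.
#'
#' @inheritParams naive_qgram_hash
#' @return A `hash_stream`: the seed, a character vector of decimal hash
#'   values in position order, a parallel validity vector, and the hash bit
#'   width `2 * weight`.
#' @seealso [fish_hash_stream()] for the block-indexed equivalent.
#' @export
naive_hash_stream <- function(x, seed) {
  x <- as_encoded(x)
  seed <- as_seed(seed)
  r <- cpp_naive_stream(x$codes, x$valid, seed$shape,
                        2L * seed$m[seed$shape + 1L], seed$span)
  new_hash_stream(seed, r$hashes, r$valid, 2L * seed$weight)
}

#' Rolling hash table of all contiguous l-mers
#'
#' Entry `i` (0-based) holds the 2-bit concatenation hash of
#' `x[i .. i+l-1]`, first symbol in the least-significant bits. The first
#' window is assembled symbol by symbol; each subsequent window is derived
#' in constant time from its predecessor
#' (`h' = (h >> 2) | (code_new << 2(l-1))`), exploiting the `l - 1` symbol
#' overlap of consecutive l-mers. Entry validity is the AND of the window's
#' symbol validity.
#'
#' @param x An `encoded_sequence` (or a sequence string).
#' @param l Window length, `1 <= l <= n`.
#' @return An object of class `kmer_table` with fields `l`, `hashes`
#'   (decimal strings, length `n - l + 1`), `valid`, and `width = 2 * l`.
#' @examples
#' t5 <- build_kmer_table("ACTGACTGGATTGACTCC", 5)
#' hash_bits(t5)[9]  # entry at position 8: "1011110010"
#' @export
build_kmer_table <- function(x, l) {
  x <- as_encoded(x)
  l <- as.integer(l)
  if (length(l) != 1L || is.na(l) || l < 1L)
    stop("`l` must be a positive integer")
  if (l > 32L)
    stop("`l` exceeds the supported maximum of 32")
  if (l > x$length)
    stop("`l` (", l, ") exceeds the sequence length (", x$length, ")")
  r <- cpp_kmer_table(x$codes, x$valid, l)
  structure(
    list(l = l, hashes = r$hashes, valid = r$valid, width = 2L * l),
    class = "kmer_table"
  )
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("<kmer_table: l=%d, %d entries, %d invalid>\n",
              x$l, length(x$hashes), sum(!x$valid)))
  invisible(x)
}

# Build the k-mer tables needed for a set of block lengths, as a list named
# by length. Lengths exceeding the sequence are skipped (any seed containing
# such a block has span > n and yields an empty stream anyway).
build_block_tables <- function(enc, lengths) {
  lengths <- sort(unique(as.integer(lengths)))
  lengths <- lengths[lengths <= enc$length]
  tabs <- lapply(lengths, function(l) build_kmer_table(enc, l))
  names(tabs) <- as.character(lengths)
  tabs
}

#' Spaced-seed hash stream via block-indexed recombination
#'
#' The block-indexed fast path: the seed is decomposed into unit blocks, one
#' rolling l-mer table is built (or taken from `tables`) per distinct block
#' length, and the hash at position `i` is assembled as the bitwise OR over
#' blocks `j` of `T_l[i + b_j] << 2 * m(b_j)`. The result is bitwise
#' identical to [naive_hash_stream()] at every position.
#'
#' @inheritParams naive_qgram_hash
#' @param tables Optional pre-built tables: a list of `kmer_table` objects
#'   named by their length (as produced for instance by a multi-seed run).
#'   Must cover every distinct block length of the seed and stem from the
#'   same sequence; missing lengths are an error. `NULL` (default) builds
#'   the needed tables on the fly.
#' @return A `hash_stream` (see [naive_hash_stream()]).
#' @examples
#' fish <- fish_hash_stream("ACTGACTGGATTGAC", "1101110011111")
#' hash_bits(fish)  # three 20-bit codewords
#' @export
fish_hash_stream <- function(x, seed, tables = NULL) {
  x <- as_encoded(x)
  seed <- as_seed(seed)
  if (x$length < seed$span)
    return(new_hash_stream(seed, character(0), logical(0), 2L * seed$weight))
  d <- decompose_blocks(seed)
  if (is.null(tables)) {
    tables <- build_block_tables(x, d$lengths)
  } else {
    missing <- setdiff(d$lengths, as.integer(names(tables)))
    if (length(missing))
      stop("no k-mer table supplied for block length(s) ",
           paste(sort(missing), collapse = ", "))
    for (l in unique(d$lengths)) {
      tab <- tables[[as.character(l)]]
      if (!inherits(tab, "kmer_table") || tab$l != l)
        stop("table entry '", l, "' is not a kmer_table of length ", l)
      if (length(tab$hashes) != x$length - l + 1L)
        stop("k-mer table for length ", l,
             " does not match the sequence length")
    }
  }
  dist_len <- sort(unique(d$lengths))
  tab_list <- lapply(dist_len, function(l) tables[[as.character(l)]]$hashes)
  val_list <- lapply(dist_len, function(l) tables[[as.character(l)]]$valid)
  block_tab <- match(d$lengths, dist_len) - 1L
  shifts <- 2L * seed$m[d$starts + 1L]
  r <- cpp_fish_stream(tab_list, val_list, block_tab, d$starts, shifts,
                       seed$span, x$length)
  new_hash_stream(seed, r$hashes, r$valid, 2L * seed$weight)
}

#' Hash streams for multiple seeds with shared k-mer tables
#'
#' Builds each l-mer table in the plan's union of block lengths exactly once
#' and reuses it across all seeds that contain a block of that length. Each
#' returned stream is identical to the corresponding single-seed
#' [fish_hash_stream()] run.
#'
#' @param x An `encoded_sequence` (or a sequence string).
#' @param plan A `multi_seed_plan` from [plan_multi()], or a list of seeds /
#'   pattern strings (a plan is then derived).
#' @param verbose Emit a message with the number of tables built.
#' @return A list of `hash_stream` objects, one per seed in plan order, with
#'   attribute `tables_built` — the number of k-mer tables constructed,
#'   `length(plan$union_lengths)` for inputs long enough to need them all.
#' @export
fish_multi_hash_stream <- function(x, plan, verbose = FALSE) {
  x <- as_encoded(x)
  if (!inherits(plan, "multi_seed_plan")) plan <- plan_multi(plan)
  tables <- build_block_tables(x, plan$union_lengths)
  if (verbose)
    message("built ", length(tables), " shared k-mer table(s) for lengths {",
            paste(names(tables), collapse = ","), "}")
  streams <- lapply(plan$seeds, function(s) fish_hash_stream(x, s, tables))
  attr(streams, "tables_built") <- length(tables)
  streams
}

#' Render hashes as binary codewords
#'
#' Returns the big-endian binary string of each hash value, zero-padded to
#' the stream's bit width (`2 * weight` for seed streams, `2 * l` for k-mer
#' tables). Because the first matched symbol sits in the least-significant
#' bits, the rendering lists the *last* matched symbol's code leftmost.
#'
#' @param x A `hash_stream`, a `kmer_table`, or a character vector of
#'   decimal hash values (then `width` is required).
#' @param width Bit width for the character method, 1..64.
#' @return A character vector of `0`/`1` strings.
#' @export
hash_bits <- function(x, width = NULL) {
  if (inherits(x, "hash_stream") || inherits(x, "kmer_table")) {
    w <- if (!is.null(width)) width else x$width
    return(cpp_bits(x$hashes, as.integer(w)))
  }
  if (is.character(x)) {
    if (is.null(width)) stop("`width` is required for bare hash values")
    return(cpp_bits(x, as.integer(width)))
  }
  stop("cannot render object of class ", paste(class(x), collapse = "/"))
}
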