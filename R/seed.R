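#' Parse and validate a spaced seed
#'
#' A spaced seed is a binary pattern over `{0,1}` in which `1` marks a match
#' position and `0` a don't-care. The seed's *shape* is the 0-based offset set
#' of its 1s, its *weight* the number of 1s, and its *span* the pattern
#' length. A valid seed begins and ends with `1`. Patterns consisting only of
#' 1s (plain k-mers) are accepted as degenerate seeds, for which block-indexed
#' hashing reduces to a single k-mer table lookup.
#'
#' The maximum supported weight is 32, so that every hash fits a 64-bit word
#' at 2 bits per nucleotide; heavier patterns are rejected rather than
#' silently overflowing.
#'
#' @param pattern A single string over `{0,1}`, e.g. `"1101110011111"`.
#' @return An object of class `spaced_seed` with fields:
#'   \describe{
#'     \item{pattern}{the input pattern}
#'     \item{shape}{integer vector of 0-based offsets of the 1s}
#'     \item{weight}{number of match positions, `length(shape)`}
#'     \item{span}{pattern length, `max(shape) + 1`}
#'     \item{m}{integer vector of length `span`; `m[k + 1]` is the number of
#'       1s strictly left of offset `k`, so `2 * m[k + 1]` is the bit shift
#'       of offset `k`'s code in the hash}
#'   }
#' @examples
#' s <- parse_seed("1101110011111")
#' s$weight  # 10
#' s$span    # 13
#' @seealso [decompose_blocks()], [plan_multi()]
#' @export
parse_seed <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern))
    stop("`pattern` must be a single string")
  if (nchar(pattern) == 0L)
    stop("seed pattern is empty")
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% c("0", "1")))
    stop("seed pattern contains characters other than 0/1: ",
         paste(unique(setdiff(chars, c("0", "1"))), collapse = ", "))
  if (chars[1L] != "1")
    stop("seed pattern must begin with 1")
  if (chars[length(chars)] != "1")
    stop("seed pattern must end with 1")
  bits <- as.integer(chars == "1")
  shape <- which(bits == 1L) - 1L
  weight <- length(shape)
  if (weight > 32L)
    stop("seed weight ", weight, " exceeds the supported maximum of 32 ",
         "(hashes are 64-bit words at 2 bits per symbol)")
  span <- length(bits)
  m <- cumsum(c(0L, bits[-span]))
  structure(
    list(pattern = pattern, shape = shape, weight = weight,
         span = span, m = m),
    class = "spaced_seed"
  )
}

#' @export
format.spaced_seed <- function(x, ...) {
  sprintf("<spaced_seed %s  W=%d span=%d>", x$pattern, x$weight, x$span)
}

#' @export
print.spaced_seed <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.character.spaced_seed <- function(x, ...) x$pattern

# Accept either a pattern string or an already-parsed seed.
as_seed <- function(seed) {
  if (inherits(seed, "spaced_seed")) seed else parse_seed(seed)
}

#' Decompose a spaced seed into its unit blocks
#'
#' A *unit block* is a maximal run of consecutive 1s in the seed pattern;
#' each block of length `l` intercepts a contiguous l-mer of the sequence.
#' Block-indexed hashing looks each block's hash up in the l-mer table of its
#' length and recombines the pieces with shifts and bitwise OR.
#'
#' @param seed A `spaced_seed` (or a pattern string).
#' @return An object of class `block_decomposition` with fields `starts`
#'   (0-based block start offsets, first always 0) and `lengths` (parallel
#'   block lengths, summing to the seed weight), plus the originating
#'   `pattern`.
#' @examples
#' decompose_blocks("1101110011111")  # starts 0,3,8; lengths 2,3,5
#' @export
decompose_blocks <- function(seed) {
  seed <- as_seed(seed)
  bits <- as.integer(strsplit(seed$pattern, "", fixed = TRUE)[[1L]] == "1")
  r <- rle(bits)
  ends <- cumsum(r$lengths)
  starts_all <- ends - r$lengths  # 0-based run starts
  ones <- r$values == 1L
  structure(
    list(starts = as.integer(starts_all[ones]),
         lengths = as.integer(r$lengths[ones]),
         pattern = seed$pattern),
    class = "block_decomposition"
  )
}

#' @export
print.block_decomposition <- function(x, ...) {
  cat(sprintf("<block_decomposition of %s>\n", x$pattern))
  cat("  starts : {", paste(x$starts, collapse = ","), "}\n", sep = "")
  cat("  lengths: {", paste(x$lengths, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Plan shared-table hashing for multiple spaced seeds
#'
#' When several seeds are hashed over the same sequence, seeds sharing a unit
#' block length can share the corresponding l-mer table. The plan records the
#' union of block lengths across seeds (each table is built once) and, per
#' seed, the recipe used to recombine table lookups: one `(start, length,
#' shift)` triple per block, with `shift = 2 * m(start)`.
#'
#' @param seeds A list of `spaced_seed` objects (or pattern strings).
#' @return An object of class `multi_seed_plan` with fields `union_lengths`
#'   (sorted distinct block lengths across all seeds), `recipes` (per-seed
#'   data frame with columns `start`, `length`, `shift`) and `seeds`.
#' @examples
#' plan <- plan_multi(list("1101110011111", "110111"))
#' plan$union_lengths  # 2 3 5
#' @export
plan_multi <- function(seeds) {
  if (inherits(seeds, "spaced_seed") || is.character(seeds))
    seeds <- as.list(seeds)
  if (length(seeds) == 0L)
    stop("at least one seed is required")
  seeds <- lapply(seeds, as_seed)
  recipes <- lapply(seeds, function(s) {
    d <- decompose_blocks(s)
    data.frame(start = d$starts, length = d$lengths,
               shift = 2L * s$m[d$starts + 1L])
  })
  union_lengths <- sort(unique(unlist(lapply(recipes, `[[`, "length"))))
  structure(
    list(union_lengths = as.integer(union_lengths),
         recipes = recipes, seeds = seeds),
    class = "multi_seed_plan"
  )
}

#' @export
print.multi_seed_plan <- function(x, ...) {
  cat(sprintf("<multi_seed_plan: %d seed(s), shared table lengths {%s}>\n",
              length(x$seeds), paste(x$union_lengths, collapse = ",")))
  invisible(x)
}

#' Read spaced seed patterns from a text file
#'
#' One pattern per line; `#` starts a comment (whole-line or trailing);
#' blank lines are ignored.
#'
#' @param path Path to the seeds file.
#' @return A list of `spaced_seed` objects, in file order.
#' @export
read_seed_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    stop("no seed patterns found in ", path)
  lapply(lines, parse_seed)
}

#' Extract the Q-gram at a position
#'
#' The Q-gram at (0-based) position `i` is the length-W string formed by the
#' sequence symbols at offsets `i + shape`.
#'
#' @param x A sequence string.
#' @param seed A `spaced_seed` (or pattern string).
#' @param i 0-based start position, `0 <= i <= nchar(x) - span`.
#' @return A string of length `seed$weight`.
#' @examples
#' qgram("ACTGACTGGATTGAC", "1101110011111", 0)  # "ACGACGATTG"
#' @export
qgram <- function(x, seed, i) {
  seed <- as_seed(seed)
  n <- nchar(x)
  if (i < 0 || i > n - seed$span)
    stop("position ", i, " out of range 0..", n - seed$span)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  paste(chars[i + seed$shape + 1L], collapse = "")
}
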