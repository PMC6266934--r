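#' Simulate random DNA reads
#'
#' Generates uniform random reads for exercising the hashing machinery.
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc_content / 2` and
#' `P(A) = P(T) = (1 - gc_content) / 2`; each base is then independently
#' replaced by `N` with probability `n_rate`. The generator uses R's
#' Mersenne-Twister stream seeded with `rng_seed`, which is
#' platform-independent, so a given configuration reproduces byte-identical
#' reads everywhere. Sequencing-error profiles are deliberately not
#' emulated: a substituted base is just another base to a hash function, so
#' uniform reads exercise the algorithm fully.
#'
#' @param n_reads Number of reads (>= 0).
#' @param read_length Length of each read (>= 0).
#' @param rng_seed Integer seed; same seed, same reads.
#' @param gc_content Expected G+C fraction in `[0, 1]`, default 0.5.
#' @param n_rate Probability a base is replaced by `N`, default 0.
#' @return A data frame with columns `id` (`read_000001`, ...) and
#'   `sequence`.
#' @examples
#' reads <- simulate_reads(3, 20, rng_seed = 42)
#' reads$sequence
#' @export
simulate_reads <- function(n_reads, read_length, rng_seed,
                           gc_content = 0.5, n_rate = 0) {
  n_reads <- as.integer(n_reads)
  read_length <- as.integer(read_length)
  stopifnot(length(n_reads) == 1L, !is.na(n_reads), n_reads >= 0L,
            length(read_length) == 1L, !is.na(read_length), read_length >= 0L,
            gc_content >= 0, gc_content <= 1, n_rate >= 0, n_rate <= 1)
  set.seed(as.integer(rng_seed))
  total <- n_reads * read_length
  ids <- sprintf("read_%06d", seq_len(n_reads))
  if (total == 0L) {
    return(data.frame(id = ids, sequence = rep("", n_reads),
                      stringsAsFactors = FALSE))
  }
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  bases <- sample(names(p), total, replace = TRUE, prob = p)
  if (n_rate > 0)
    bases[runif(total) < n_rate] <- "N"
  seqs <- vapply(seq_len(n_reads), function(i) {
    paste(bases[((i - 1L) * read_length + 1L):(i * read_length)],
          collapse = "")
  }, character(1))
  data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
}

#' The nine experiment seeds (Q1-Q9)
#'
#' The widely used benchmark set of nine spaced seeds, three per design
#' criterion (maximal hit probability, minimal overlap complexity, maximal
#' sensitivity). All nine have weight 22 and span 31. A copy also ships as
#' the plain-text fixture `system.file("extdata", "seeds_q1_q9.txt",
#' package = "seedhash")`.
#'
#' @return A named list (`Q1` ... `Q9`) of `spaced_seed` objects.
#' @export
table2_seeds <- function() {
  patterns <- c(
    Q1 = "1111011101110010111001011011111",
    Q2 = "1111101011100101101110011011111",
    Q3 = "1111101001110101101100111011111",
    Q4 = "1111010111010011001110111110111",
    Q5 = "1110111011101111010010110011111",
    Q6 = "1111101001011100111110101101111",
    Q7 = "1111011110011010111110101011011",
    Q8 = "1110101011101100110100111111111",
    Q9 = "1111110101101011100111011001111"
  )
  lapply(as.list(patterns), parse_seed)
}
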