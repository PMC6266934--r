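#' Read DNA sequences from FASTA or FASTQ
#'
#' FASTA goes through Biostrings' reader; FASTQ uses a strict 4-line-record
#' parser (Biostrings' FASTQ reader mis-handles zero-length reads, which are
#' legal and do occur after trimming). The format is auto-detected from the
#' first character of the file (`>` FASTA, `@` FASTQ) unless given
#' explicitly; gzip-compressed input is accepted. FASTQ qualities are parsed
#' and discarded.
#'
#' @param path Input file path.
#' @param format `"auto"` (default), `"fasta"` or `"fastq"`.
#' @return A data frame with character columns `id` and `sequence`
#'   (uppercased), one row per record in file order.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read input file: ", path)
  if (format == "auto") {
    con <- gzfile(path, "rt")
    first <- readLines(con, n = 1L, warn = FALSE)
    close(con)
    if (length(first) == 0L) {
      format <- "fasta"  # empty file: zero records either way
    } else if (startsWith(first, ">")) {
      format <- "fasta"
    } else if (startsWith(first, "@")) {
      format <- "fastq"
    } else {
      stop("cannot auto-detect format of ", path,
           ": first character is neither '>' nor '@'")
    }
  }
  if (format == "fastq") return(read_fastq(path))
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  data.frame(id = names(seqs),
             sequence = toupper(as.character(seqs)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Strict 4-line-record FASTQ parser (sequence and quality on single lines,
# the dominant layout for NGS reads). Errors name the offending record.
read_fastq <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ ", path, ": line count is not a multiple of 4")
  n <- length(lines) %/% 4L
  ids <- character(n)
  seqs <- character(n)
  for (i in seq_len(n)) {
    b <- 4L * (i - 1L)
    if (!startsWith(lines[b + 1L], "@"))
      stop("malformed FASTQ record ", i, ": header does not start with '@'")
    if (!startsWith(lines[b + 3L], "+"))
      stop("malformed FASTQ record ", i, ": separator does not start with '+'")
    if (nchar(lines[b + 2L]) != nchar(lines[b + 4L]))
      stop("malformed FASTQ record ", i,
           ": sequence and quality lengths differ")
    ids[i] <- sub("^@", "", lines[b + 1L])
    seqs[i] <- toupper(lines[b + 2L])
  }
  data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA or FASTQ
#'
#' FASTQ output assigns the constant quality character `I` to every base.
#'
#' @param records Data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @param format `"fasta"` (default) or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_reads <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::DNAStringSet(records$sequence)
  names(x) <- records$id
  if (format == "fastq") {
    quals <- Biostrings::BStringSet(strrep("I", nchar(records$sequence)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  }
  invisible(path)
}

#' Hash a set of records against a set of seeds
#'
#' Convenience driver used by the writers and the CLI: hashes every record
#' with every seed and returns the streams in a flat list.
#'
#' @param records Data frame with columns `id` and `sequence`.
#' @param seeds A list of `spaced_seed` objects or pattern strings.
#' @param method `"fish"` (block-indexed, default), `"naive"`, or `"multi"`
#'   (block-indexed with k-mer tables shared across seeds).
#' @return A list of entries `list(record_id, seed_index, stream)`, ordered
#'   by record then seed; attribute `tables_built` totals the k-mer tables
#'   constructed (multi method only).
#' @export
collect_hash_streams <- function(records, seeds,
                                 method = c("fish", "naive", "multi")) {
  method <- match.arg(method)
  if (inherits(seeds, "spaced_seed") || is.character(seeds))
    seeds <- as.list(seeds)
  seeds <- lapply(seeds, as_seed)
  plan <- if (method == "multi") plan_multi(seeds) else NULL
  entries <- list()
  tables_built <- 0L
  for (r in seq_len(nrow(records))) {
    enc <- encode_sequence(records$sequence[r])
    streams <- switch(method,
      naive = lapply(seeds, function(s) naive_hash_stream(enc, s)),
      fish  = lapply(seeds, function(s) fish_hash_stream(enc, s)),
      multi = {
        st <- fish_multi_hash_stream(enc, plan)
        tables_built <- tables_built + attr(st, "tables_built")
        st
      })
    for (s in seq_along(seeds)) {
      entries[[length(entries) + 1L]] <-
        list(record_id = records$id[r], seed_index = s,
             stream = streams[[s]])
    }
  }
  attr(entries, "tables_built") <- tables_built
  entries
}

#' Write hash streams to TSV or a binary container
#'
#' TSV mode emits a header and one line per (record, seed, position):
#' `record_id`, `seed_index` (1-based), `pos` (0-based), `hash` (unsigned
#' decimal) and `valid` (1/0). Invalid positions keep their computed hash
#' and carry the flag — no sentinel values. Binary mode writes a
#' self-describing little-endian container (magic `FISHHS01`, format
#' version, per-entry record id, seed pattern and 64-bit hash words) that
#' [read_hash_stream()] restores bit-exactly.
#'
#' @param entries A list of `list(record_id, seed_index, stream)` entries,
#'   as produced by [collect_hash_streams()].
#' @param path Output path.
#' @param mode `"tsv"` (default) or `"binary"`.
#' @return Invisibly, a list with `streams` (entry count) and `positions`
#'   (total hash count written).
#' @export
write_hash_stream <- function(entries, path, mode = c("tsv", "binary")) {
  mode <- match.arg(mode)
  positions <- sum(vapply(entries, function(e) length(e$stream$hashes), 0L))
  if (mode == "tsv") {
    rows <- lapply(entries, function(e) {
      n <- length(e$stream$hashes)
      if (n == 0L) return(NULL)
      data.frame(record_id = e$record_id, seed_index = e$seed_index,
                 pos = seq_len(n) - 1L, hash = e$stream$hashes,
                 valid = as.integer(e$stream$valid),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, c(rows, list(
      data.frame(record_id = character(0), seed_index = integer(0),
                 pos = integer(0), hash = character(0), valid = integer(0),
                 stringsAsFactors = FALSE))))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeBin(charToRaw("FISHHS01"), con)
    writeBin(1L, con, size = 4L, endian = "little")           # version
    writeBin(length(entries), con, size = 4L, endian = "little")
    for (e in entries) {
      id_raw <- charToRaw(e$record_id)
      pat_raw <- charToRaw(e$stream$seed$pattern)
      writeBin(length(id_raw), con, size = 4L, endian = "little")
      writeBin(id_raw, con)
      writeBin(e$seed_index, con, size = 4L, endian = "little")
      writeBin(length(pat_raw), con, size = 4L, endian = "little")
      writeBin(pat_raw, con)
      writeBin(as.integer(e$stream$width), con, size = 4L, endian = "little")
      n <- length(e$stream$hashes)
      writeBin(n, con, size = 4L, endian = "little")
      if (n > 0L) {
        writeBin(cpp_u64_to_raw(e$stream$hashes), con)
        writeBin(as.raw(as.integer(e$stream$valid)), con)
      }
    }
  }
  invisible(list(streams = length(entries), positions = positions))
}

#' Read hash streams back from the binary container
#'
#' @param path Path to a file written by [write_hash_stream()] in binary
#'   mode.
#' @return A list of `list(record_id, seed_index, stream)` entries.
#' @export
read_hash_stream <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (magic != "FISHHS01") stop("not a seedhash binary container: ", path)
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (version != 1L) stop("unsupported container version: ", version)
  n_entries <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  entries <- vector("list", n_entries)
  for (i in seq_len(n_entries)) {
    id_len <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    record_id <- rawToChar(readBin(con, "raw", id_len))
    seed_index <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    pat_len <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    pattern <- rawToChar(readBin(con, "raw", pat_len))
    width <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (n > 0L) {
      hashes <- cpp_raw_to_u64(readBin(con, "raw", 8L * n))
      valid <- as.logical(as.integer(readBin(con, "raw", n)))
    } else {
      hashes <- character(0)
      valid <- logical(0)
    }
    entries[[i]] <- list(
      record_id = record_id, seed_index = seed_index,
      stream = new_hash_stream(parse_seed(pattern), hashes, valid, width))
  }
  entries
}
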