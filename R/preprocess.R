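#' Detect a 3'-terminal poly(A) tail in a read
#'
#' Libraries prepared with single-tube polyadenylation chemistry carry an
#' enzymatically added adenosine run at every read's 3' end. This function
#' decomposes a read into a 5' insert and a 3' poly(A) tail, and applies the
#' tail-length selection filter (reads whose terminal A-run is shorter than
#' `min_tail` are rejected from further analysis).
#'
#' The tail is the maximal 3'-terminal run of `A`. With
#' `max_interruptions > 0` the run may contain that many isolated (never
#' adjacent) non-A bases; the 5'-most base of the reported tail is always an
#' `A`, so interruption credits are never spent extending past the true run
#' boundary. `N` bases never count as `A`.
#'
#' @param read a list with `read_id`, `sequence` and `qualities` (see
#'   [raw_read()]), or a plain character sequence.
#' @param min_tail minimum terminal A-run length to pass the tail filter.
#'   The default 9 implements selection of reads with more than eight
#'   terminal adenosines.
#' @param max_interruptions maximum number of isolated non-A bases tolerated
#'   inside the tail (default 0: a strict terminal A-run).
#' @param min_insert minimum insert length used to set
#'   `passed_insert_filter`; the default 18 matches the shortest alignment
#'   the downstream aligner is configured to accept, so shorter inserts are
#'   dropped before alignment.
#' @return an object of class `TailCall` with fields `tail_length`,
#'   `insert_length`, `passed_tail_filter`, `passed_insert_filter`.
#' @examples
#' detect_tail("ACGTAAAAAAAAA")          # 9-base tail: passes
#' detect_tail("ACGTAAAAAAAA")           # 8-base tail: fails
#' @export
detect_tail <- function(read, min_tail = 9L, max_interruptions = 0L,
                        min_insert = 18L) {
  read <- as_raw_read(read)
  n <- nchar(read$sequence)
  if (n < 1L) stop("detect_tail: empty sequence for read '", read$read_id, "'")
  if (min_tail < 1L) stop("detect_tail: min_tail must be >= 1")
  tail_length <- tail_run_length(read$sequence, max_interruptions)
  insert_length <- n - tail_length
  passed_tail <- tail_length >= min_tail
  structure(list(
    tail_length = tail_length,
    insert_length = insert_length,
    passed_tail_filter = passed_tail,
    passed_insert_filter = passed_tail && insert_length >= min_insert
  ), class = "TailCall")
}

#' @export
print.TailCall <- function(x, ...) {
  cat(sprintf("TailCall: tail=%d insert=%d tail_filter=%s insert_filter=%s\n",
              x$tail_length, x$insert_length,
              x$passed_tail_filter, x$passed_insert_filter))
  invisible(x)
}

# Length of the maximal 3'-terminal A-run, allowing up to `max_interruptions`
# isolated non-A bases inside the run. The returned run always starts (5'
# side) with an A.
tail_run_length <- function(sequence, max_interruptions = 0L) {
  if (max_interruptions == 0L) {
    return(nchar(sequence) - nchar(sub("A*$", "", sequence)))
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  used <- 0L
  i <- n
  prev_non_a <- FALSE
  while (i >= 1L) {
    if (chars[i] == "A") {
      prev_non_a <- FALSE
    } else {
      if (prev_non_a || used >= max_interruptions) break
      used <- used + 1L
      prev_non_a <- TRUE
    }
    i <- i - 1L
  }
  len <- n - i
  # the tail must not begin with an interruption
  while (len > 0L && chars[n - len + 1L] != "A") len <- len - 1L
  len
}

#' Clip the poly(A) tail from a read
#'
#' Returns the 5' insert (sequence and qualities truncated together) if the
#' read passed the tail filter and the insert is at least `min_insert` bases
#' long; otherwise `NULL`. With `max_interruptions = 0` the returned insert
#' never ends in `A`, so re-running [detect_tail()] on it reports a zero
#' tail.
#'
#' @param read a raw read (see [raw_read()]).
#' @param call the `TailCall` produced from `read` by [detect_tail()].
#' @param min_insert minimum insert length to keep the read (default 18).
#' @return a raw read holding the insert, or `NULL` if the read fails
#'   either filter.
#' @export
clip_tail <- function(read, call, min_insert = 18L) {
  read <- as_raw_read(read)
  stopifnot(inherits(call, "TailCall"))
  if (!call$passed_tail_filter || call$insert_length < min_insert) return(NULL)
  raw_read(read$read_id,
           substr(read$sequence, 1L, call$insert_length),
           substr(read$qualities, 1L, call$insert_length))
}

#' Construct a raw read record
#'
#' @param read_id read identifier.
#' @param sequence base string over `{A,C,G,T,N}`.
#' @param qualities per-base quality string (Phred+33); defaults to constant
#'   high quality.
#' @return a list of class `RawRead`.
#' @export
raw_read <- function(read_id, sequence,
                     qualities = strrep("I", nchar(sequence))) {
  if (nchar(sequence) != nchar(qualities)) {
    stop("raw_read: sequence/quality length mismatch for read '", read_id, "'")
  }
  structure(list(read_id = as.character(read_id),
                 sequence = as.character(sequence),
                 qualities = as.character(qualities)),
            class = "RawRead")
}

as_raw_read <- function(x) {
  if (inherits(x, "RawRead")) return(x)
  if (is.character(x) && length(x) == 1L) return(raw_read("read", x))
  if (is.list(x) && all(c("read_id", "sequence", "qualities") %in% names(x))) {
    return(raw_read(x$read_id, x$sequence, x$qualities))
  }
  stop("cannot interpret input as a raw read")
}

#' Select, clip and filter poly(A)-tailed reads in a FASTQ file
#'
#' Streams a FASTQ file, keeps reads whose 3'-terminal A-run is at least
#' `min_tail` bases, clips the tail away, drops clipped inserts shorter than
#' `min_insert`, and writes the surviving inserts (original ids preserved)
#' to `out`. This is the read-selection step applied to raw data before
#' alignment.
#'
#' @param input path to a FASTQ file (optionally gzip-compressed).
#' @param output path for the clipped FASTQ output, or `NULL` to skip
#'   writing.
#' @param min_tail,min_insert,max_interruptions see [detect_tail()] and
#'   [clip_tail()].
#' @return an object of class `PreprocessStats`: counts `reads_in`,
#'   `reads_with_tail`, `reads_out`, a `tail_length_histogram` (over reads
#'   passing the tail filter), and the surviving read ids (`kept_ids`).
#' @export
process_fastq <- function(input, output = NULL, min_tail = 9L,
                          min_insert = 18L, max_interruptions = 0L) {
  reads <- read_fastq(input)
  res <- preprocess_reads(reads$sequence, min_tail = min_tail,
                          min_insert = min_insert,
                          max_interruptions = max_interruptions)
  keep <- res$keep
  if (!is.null(output)) {
    write_fastq(
      data.frame(read_id = reads$read_id[keep],
                 sequence = substr(reads$sequence[keep], 1L,
                                   res$insert_length[keep]),
                 qualities = substr(reads$qualities[keep], 1L,
                                    res$insert_length[keep]),
                 stringsAsFactors = FALSE),
      output)
  }
  tails <- res$tail_length[res$with_tail]
  hist <- if (length(tails)) table(tails) else table(integer(0))
  structure(list(
    reads_in = length(reads$sequence),
    reads_with_tail = sum(res$with_tail),
    reads_out = sum(keep),
    tail_length_histogram = hist,
    kept_ids = reads$read_id[keep]
  ), class = "PreprocessStats")
}

# Vectorized tail detection over many sequences.
preprocess_reads <- function(sequences, min_tail = 9L, min_insert = 18L,
                             max_interruptions = 0L) {
  if (max_interruptions == 0L) {
    tail_length <- nchar(sequences) - nchar(sub("A*$", "", sequences))
  } else {
    tail_length <- vapply(sequences, tail_run_length, integer(1),
                          max_interruptions = max_interruptions,
                          USE.NAMES = FALSE)
  }
  insert_length <- nchar(sequences) - tail_length
  with_tail <- tail_length >= min_tail
  list(tail_length = tail_length, insert_length = insert_length,
       with_tail = with_tail, keep = with_tail & insert_length >= min_insert)
}

#' @export
print.PreprocessStats <- function(x, ...) {
  cat("Poly(A)-tail preprocessing\n")
  cat(sprintf("  reads in:        %d\n", x$reads_in))
  cat(sprintf("  tail >= filter:  %d (%.1f%%)\n", x$reads_with_tail,
              100 * x$reads_with_tail / max(1L, x$reads_in)))
  cat(sprintf("  inserts kept:    %d (%.1f%%)\n", x$reads_out,
              100 * x$reads_out / max(1L, x$reads_in)))
  invisible(x)
}

#' Read a FASTQ file into a data frame
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; qualities are
#' returned as Phred+33 strings.
#'
#' @param path FASTQ path, optionally gzip-compressed.
#' @return data frame with columns `read_id`, `sequence`, `qualities`.
#' @export
read_fastq <- function(path) {
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ '", path, "': ",
                             conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(seqs))
  quals <- as.character(S4Vectors::mcols(seqs)$qualities)
  data.frame(read_id = ids, sequence = as.character(seqs),
             qualities = quals, stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#'
#' @param reads data frame with columns `read_id`, `sequence`, `qualities`.
#' @param path output path; a `.gz` suffix enables gzip compression.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  Biostrings::writeXStringSet(
    seqs, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qualities),
    compress = grepl("\\.gz$", path))
  invisible(path)
}
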