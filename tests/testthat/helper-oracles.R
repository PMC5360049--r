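# Independent brute-force oracles used across the suite. These never call
# into the package's interval or trimming code paths: tail selection is a
# single regular expression, interval arithmetic is per-base set logic on
# plain logical vectors.

suppressPackageStartupMessages({
  library(GenomicRanges)
})

# A read survives iff it has >= min_tail terminal As preceded by an insert
# of >= min_insert bases whose last base is not A (the tail is maximal).
oracle_survives <- function(sequences, min_tail = 9, min_insert = 18) {
  grepl(sprintf("^.{%d,}[^A]A{%d,}$", min_insert - 1, min_tail), sequences)
}

random_reads <- function(n, min_len = 10, max_len = 60, p_tail = 0.5) {
  lens <- sample(min_len:max_len, n, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    "")
  # append explicit tails to half the reads so both branches are exercised
  tail_on <- runif(n) < p_tail
  tails <- sample(0:25, n, replace = TRUE)
  seqs[tail_on] <- paste0(seqs[tail_on], strrep("A", tails[tail_on]))
  seqs
}

# per-base occupancy of a GRanges on one chromosome, as a strand-keyed list
# of logical vectors over positions 1..N (1-based)
occupancy <- function(gr, N, chrom = "chr1") {
  out <- list("+" = logical(N), "-" = logical(N))
  keep <- as.character(seqnames(gr)) == chrom
  st <- as.character(strand(gr))[keep]
  s1 <- start(gr)[keep]
  e1 <- end(gr)[keep]
  for (i in seq_along(st)) {
    idx <- s1[i]:e1[i]
    if (st[i] %in% c("+", "*")) out[["+"]][idx] <- TRUE
    if (st[i] %in% c("-", "*")) out[["-"]][idx] <- TRUE
  }
  out
}

random_granges <- function(n, N = 1e5, chrom = "chr1",
                           strands = c("+", "-"), max_w = 500) {
  st <- sample(seq_len(N - max_w), n, replace = TRUE)
  w <- sample.int(max_w, n, replace = TRUE)
  GRanges(chrom, IRanges(st, st + w - 1L),
          strand = sample(strands, n, replace = TRUE))
}

# brute-force read categorization: first layer (in order) with >= min_ov
# same-strand overlapping bases
oracle_categorize <- function(aln, layers, N, chrom = "chr1", min_ov = 1) {
  occ <- lapply(layers, occupancy, N = N, chrom = chrom)
  vapply(seq_along(aln), function(i) {
    s <- as.character(strand(aln))[i]
    idx <- start(aln)[i]:end(aln)[i]
    for (nm in names(layers)) {
      hit <- if (s == "*") occ[[nm]][["+"]][idx] | occ[[nm]][["-"]][idx]
             else occ[[nm]][[s]][idx]
      if (sum(hit) >= min_ov) return(nm)
    }
    "unannotated"
  }, "")
}

# shared toy reference, built once per test run
toy <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) ref <<- stakit::build_toy_reference(1)
    ref
  }
})
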