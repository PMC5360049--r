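#' Gene-body coverage profile over transcript length percentiles
#'
#' Aggregates read depth over the exonic body of each eligible transcript,
#' rescaled to 100 length-percentile bins oriented 5' to 3' (bin 100 is the
#' transcript's 3' end, where poly(A)-anchored chemistry concentrates its
#' reads). Depth within each transcript is averaged per bin, bins are
#' summed over transcripts and normalized to total 1. Only reads on the
#' transcript's own strand contribute to its depth — the protocol is
#' stranded, and antisense overlaps would otherwise contaminate the
#' profiles of genes with antisense partners.
#'
#' @param alignments `GRanges` of primary alignments.
#' @param transcripts a `TranscriptSet` (see [parse_gtf()]) or an
#'   `AnnotationBundle`.
#' @param min_len minimum exonic length of a transcript to be included
#'   (default 100, one base per percentile bin).
#' @return object of class `GeneBodyProfile`: numeric vector `bins` of
#'   length 100 summing to 1 (all zero if there is no coverage), and
#'   `n_transcripts` used.
#' @export
gene_body_coverage <- function(alignments, transcripts, min_len = 100L) {
  if (inherits(transcripts, "AnnotationBundle")) {
    transcripts <- transcripts$transcripts
  }
  stopifnot(inherits(transcripts, "TranscriptSet"))
  exl <- transcripts$exons
  strand_of <- stats::setNames(transcripts$transcripts$strand,
                               transcripts$transcripts$transcript_id)
  aln_strand <- as.character(GenomicRanges::strand(alignments))
  cov_by_strand <- list(
    "+" = GenomicRanges::coverage(alignments[aln_strand != "-"]),
    "-" = GenomicRanges::coverage(alignments[aln_strand != "+"]))
  bins <- numeric(100L)
  used <- 0L
  for (tx in names(exl)) {
    ex <- exl[[tx]]
    L <- sum(GenomicRanges::width(ex))
    if (L < min_len) next
    chrom <- as.character(GenomicRanges::seqnames(ex))[1]
    cov <- cov_by_strand[[strand_of[[tx]]]]
    if (is.null(cov) || !chrom %in% names(cov)) next
    cr <- cov[[chrom]]
    clen <- length(cr)
    depth <- unlist(lapply(seq_along(ex), function(i) {
      s <- GenomicRanges::start(ex)[i]
      e <- GenomicRanges::end(ex)[i]
      if (s > clen) return(numeric(e - s + 1L))
      d <- as.numeric(cr[s:min(e, clen)])
      if (e > clen) d <- c(d, numeric(e - clen))
      d
    }))
    if (identical(strand_of[[tx]], "-")) depth <- rev(depth)
    bin_of <- ceiling(seq_len(L) * 100 / L)
    bins <- bins + as.numeric(tapply(depth, bin_of, mean))
    used <- used + 1L
  }
  if (used == 0L) warning("gene_body_coverage: no eligible transcript")
  total <- sum(bins)
  structure(list(bins = if (total > 0) bins / total else bins,
                 n_transcripts = used),
            class = "GeneBodyProfile")
}

#' @export
print.GeneBodyProfile <- function(x, ...) {
  cat(sprintf("Gene-body coverage over %d transcripts\n", x$n_transcripts))
  cat(sprintf("  5' half (bins 1-50):   %.3f\n", sum(x$bins[1:50])))
  cat(sprintf("  3' half (bins 51-100): %.3f\n", sum(x$bins[51:100])))
  invisible(x)
}

#' Plot a gene-body coverage profile
#'
#' @param x a `GeneBodyProfile`.
#' @param ... passed to [plot()].
#' @export
plot.GeneBodyProfile <- function(x, ...) {
  plot(seq_len(100), x$bins, type = "l",
       xlab = "gene body percentile (5' → 3')",
       ylab = "fraction of coverage", ...)
  invisible(x)
}

#' RPM-normalized stranded coverage tracks
#'
#' Computes per-strand per-base depth scaled by `1e6 / aligned_total`
#' (reads per million), represented as merged constant-value intervals.
#' The reverse-strand track is kept separate; signs are a display
#' convention, values are positive in both tracks.
#'
#' @param alignments `GRanges` of primary alignments.
#' @param aligned_total total aligned reads for normalization (defaults to
#'   `length(alignments)`).
#' @return object of class `CoverageTrack`: list with `fwd` and `rev`
#'   data frames (`chrom`, `start` 0-based, `end`, `value`), and
#'   `aligned_total`.
#' @export
rpm_tracks <- function(alignments, aligned_total = length(alignments)) {
  if (aligned_total == 0L) stop("rpm_tracks: aligned_total is zero")
  scale <- 1e6 / aligned_total
  one <- function(strand) {
    sel <- alignments[as.character(GenomicRanges::strand(alignments)) ==
                        strand]
    if (length(sel) == 0L) {
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), value = numeric(0)))
    }
    gr <- as(GenomicRanges::coverage(sel), "GRanges")
    gr <- gr[GenomicRanges::mcols(gr)$score > 0]
    out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = start0(gr), end = GenomicRanges::end(gr),
                      value = GenomicRanges::mcols(gr)$score * scale,
                      stringsAsFactors = FALSE)
    out[order(out$chrom, out$start), , drop = FALSE]
  }
  structure(list(fwd = one("+"), rev = one("-"),
                 aligned_total = aligned_total),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("RPM coverage track (aligned_total=%d)\n", x$aligned_total))
  cat(sprintf("  forward: %d intervals, mass %.1f\n", nrow(x$fwd),
              sum(x$fwd$value * (x$fwd$end - x$fwd$start))))
  cat(sprintf("  reverse: %d intervals, mass %.1f\n", nrow(x$rev),
              sum(x$rev$value * (x$rev$end - x$rev$start))))
  invisible(x)
}

#' Write a coverage track as a pair of bedGraph files
#'
#' Emits `<prefix>.fwd.bedGraph` and `<prefix>.rev.bedGraph` with 0-based
#' half-open intervals, fixed 6-decimal values and deterministic
#' chromosome ordering, so output is byte-identical across runs.
#'
#' @param track a `CoverageTrack`.
#' @param prefix output path prefix.
#' @return the two file paths, invisibly.
#' @export
write_bedgraph <- function(track, prefix) {
  stopifnot(inherits(track, "CoverageTrack"))
  emit <- function(df, path) {
    writeLines(sprintf("%s\t%d\t%d\t%.6f", df$chrom, df$start, df$end,
                       df$value), path)
    path
  }
  paths <- c(emit(track$fwd, paste0(prefix, ".fwd.bedGraph")),
             emit(track$rev, paste0(prefix, ".rev.bedGraph")))
  invisible(paths)
}

#' Combined library composition report
#'
#' Merges the per-stage summaries of one library into a single document:
#' preprocessing survival, category distribution, biotype shares of exon
#' reads, and mature-miRNA recovery. Every percentage is recomputable from
#' the raw counts included alongside it.
#'
#' @param library_id library identifier carried into the report.
#' @param preprocess a `PreprocessStats` (optional).
#' @param categories a `CategoryCounts` (optional).
#' @param biotypes a `BiotypeSummary` (optional).
#' @param mature a `MatureCounts` (optional).
#' @param path if non-NULL, the report is also written there as JSON.
#' @return the report as a named list (class `CompositionReport`).
#' @export
composition_report <- function(library_id, preprocess = NULL,
                               categories = NULL, biotypes = NULL,
                               mature = NULL, path = NULL) {
  rep <- list(library_id = library_id)
  if (!is.null(preprocess)) {
    rep$preprocess <- list(
      reads_in = preprocess$reads_in,
      reads_with_tail = preprocess$reads_with_tail,
      reads_out = preprocess$reads_out,
      pct_with_tail = pct(preprocess$reads_with_tail, preprocess$reads_in),
      pct_out = pct(preprocess$reads_out, preprocess$reads_in))
  }
  if (!is.null(categories)) {
    counts <- unclass(categories)[.CATEGORIES]
    rep$categories <- c(counts,
      list(aligned_total = categories$aligned_total),
      stats::setNames(lapply(.CATEGORIES, function(k)
        pct(categories[[k]], categories$aligned_total)),
        paste0("pct_", .CATEGORIES)))
  }
  if (!is.null(biotypes)) {
    rep$biotypes <- list(exon_total = biotypes$exon_total,
                         counts = as.list(biotypes$counts),
                         pct = as.list(100 * biotypes$fractions))
  }
  if (!is.null(mature)) {
    rep$mature_mirna <- list(
      input_reads = mature$input_reads,
      removed_reads = mature$removed_reads,
      counted_reads = mature$counted_reads,
      total_mature_counts = sum(mature$counts),
      n_features = length(mature$counts))
  }
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  structure(rep, class = "CompositionReport")
}

pct <- function(num, den) if (den > 0) 100 * num / den else 0

#' @export
print.CompositionReport <- function(x, ...) {
  cat(sprintf("Composition report for library '%s'\n", x$library_id))
  if (!is.null(x$preprocess)) {
    cat(sprintf("  preprocess: %d -> %d reads (%.1f%% kept)\n",
                x$preprocess$reads_in, x$preprocess$reads_out,
                x$preprocess$pct_out))
  }
  if (!is.null(x$categories)) {
    cat(sprintf("  categories: exon %.1f%%, intron %.1f%%, tRNA %.1f%%, repeat %.1f%%, unannotated %.1f%%\n",
                x$categories$pct_exon, x$categories$pct_intron,
                x$categories$pct_trna, x$categories$pct_repeat,
                x$categories$pct_unannotated))
  }
  if (!is.null(x$mature_mirna)) {
    cat(sprintf("  mature miRNA: %d/%d reads survived non-mature removal\n",
                x$mature_mirna$input_reads - x$mature_mirna$removed_reads,
                x$mature_mirna$input_reads))
  }
  invisible(x)
}
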