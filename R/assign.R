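#' Read alignments from a BED6 file or a BAM file
#'
#' BED6 alignments (e.g. the simulator's ground-truth output) carry the
#' read id in the name column. For BAM input, only primary alignment
#' records are kept, mirroring an aligner configured to report a single
#' alignment per read; the alignment footprint is the reference span
#' (splice gaps included for overlap purposes).
#'
#' @param path BED or BAM file path.
#' @return `GRanges` with a `read_id` metadata column.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("GenomicAlignments", quietly = TRUE)) {
      stop("BAM input requires the GenomicAlignments package")
    }
    ga <- GenomicAlignments::readGAlignments(
      path,
      param = Rsamtools::ScanBamParam(
        flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                      isSupplementaryAlignment = FALSE),
        what = "qname"))
    gr <- GenomicRanges::granges(ga)
    GenomicRanges::mcols(gr)$read_id <- GenomicRanges::mcols(ga)$qname
    return(gr)
  }
  gr <- parse_bed(path)
  md <- GenomicRanges::mcols(gr)
  GenomicRanges::mcols(gr)$read_id <-
    if ("name" %in% names(md)) md$name else paste0("aln", seq_along(gr))
  gr
}

.CATEGORIES <- c("exon", "intron", "trna", "repeat", "unannotated")

#' Assign reads to genomic feature categories by layer priority
#'
#' Each alignment is assigned to the first layer, in the fixed order exon,
#' intron, tRNA, repeat, whose same-strand features overlap its footprint
#' by at least `min_overlap` bases; reads touching no layer on their own
#' strand are `unannotated`. Strandedness is enforced: an alignment that is
#' only antisense to a feature does not match it (strandless layer records,
#' strand `*`, match reads on either strand).
#'
#' @param alignments `GRanges` of primary alignments.
#' @param bundle an `AnnotationBundle`.
#' @param min_overlap minimum overlap in bases (default 1).
#' @return character vector of categories, one per alignment.
#' @export
categorize_reads <- function(alignments, bundle, min_overlap = 1L) {
  stopifnot(inherits(bundle, "AnnotationBundle"))
  cat <- rep("unannotated", length(alignments))
  layers <- list(exon = bundle$exon_index, intron = bundle$intron_index,
                 trna = bundle$trna_index, repeat_ = bundle$repeat_index)
  names(layers) <- c("exon", "intron", "trna", "repeat")
  unassigned <- rep(TRUE, length(alignments))
  for (layer in names(layers)) {
    idx <- layers[[layer]]
    if (length(idx) == 0L || !any(unassigned)) next
    hit <- GenomicRanges::countOverlaps(
      alignments, idx, minoverlap = min_overlap, ignore.strand = FALSE) > 0L
    cat[unassigned & hit] <- layer
    unassigned <- unassigned & !hit
  }
  cat
}

#' Count reads per feature category
#'
#' Each read is counted exactly once, in its priority category; the totals
#' conserve (`exon + intron + trna + repeat + unannotated == aligned_total`).
#'
#' @inheritParams categorize_reads
#' @return object of class `CategoryCounts`.
#' @export
count_categories <- function(alignments, bundle, min_overlap = 1L) {
  cats <- categorize_reads(alignments, bundle, min_overlap)
  counts <- vapply(.CATEGORIES, function(k) sum(cats == k), integer(1))
  structure(c(as.list(counts), list(aligned_total = length(alignments))),
            class = "CategoryCounts")
}

#' @export
print.CategoryCounts <- function(x, ...) {
  cat("Read categories (priority exon > intron > tRNA > repeat)\n")
  for (k in .CATEGORIES) {
    cat(sprintf("  %-12s %8d (%5.1f%%)\n", k, x[[k]],
                100 * x[[k]] / max(1L, x$aligned_total)))
  }
  cat(sprintf("  %-12s %8d\n", "total", x$aligned_total))
  invisible(x)
}

#' Count reads per gene over merged exons
#'
#' For each gene, the number of alignments overlapping its merged exon
#' intervals by at least `min_overlap` bases on the required strand. A read
#' overlapping the exons of two genes increments both (BEDTools-multicov
#' semantics), unlike category counting where each read is counted once.
#'
#' @inheritParams categorize_reads
#' @param strand_mode `"forward"` (read strand must match the gene;
#'   the library default, since clipped inserts are sense to their
#'   transcript), `"reverse"` (opposite strands match) or `"both"` (strand
#'   ignored).
#' @return named integer vector over all genes of the bundle (class
#'   `GeneCounts`).
#' @export
count_genes <- function(alignments, bundle,
                        strand_mode = c("forward", "reverse", "both"),
                        min_overlap = 1L) {
  strand_mode <- match.arg(strand_mode)
  ex <- bundle$exon_index
  aln <- alignments
  if (strand_mode == "reverse") {
    GenomicRanges::strand(aln) <- flip_strand(GenomicRanges::strand(aln))
  }
  hits <- GenomicRanges::findOverlaps(
    aln, ex, minoverlap = min_overlap,
    ignore.strand = (strand_mode == "both"))
  gid <- GenomicRanges::mcols(ex)$gene_id[S4Vectors::subjectHits(hits)]
  pairs <- unique(data.frame(read = S4Vectors::queryHits(hits), gene = gid))
  all_genes <- sort(unique(GenomicRanges::mcols(ex)$gene_id))
  counts <- stats::setNames(integer(length(all_genes)), all_genes)
  if (nrow(pairs)) {
    tab <- table(pairs$gene)
    counts[names(tab)] <- as.integer(tab)
  }
  structure(counts, class = c("GeneCounts", "integer"))
}

flip_strand <- function(s) {
  s <- as.character(s)
  out <- s
  out[s == "+"] <- "-"
  out[s == "-"] <- "+"
  out
}

#' Summarize exon-category reads by gene biotype
#'
#' Tallies exon-assigned reads by the biotype of the overlapped gene. A
#' read whose footprint overlaps same-strand exons of several genes is
#' attributed to the gene with the largest total exonic overlap, ties
#' broken by lexicographic gene id (deterministic).
#'
#' @inheritParams categorize_reads
#' @return object of class `BiotypeSummary`: `counts` (named vector by
#'   biotype), `fractions`, `exon_total`.
#' @export
summarize_biotypes <- function(alignments, bundle, min_overlap = 1L) {
  cats <- categorize_reads(alignments, bundle, min_overlap)
  exon_reads <- alignments[cats == "exon"]
  if (length(exon_reads) == 0L) {
    return(structure(list(counts = integer(0), fractions = numeric(0),
                          exon_total = 0L), class = "BiotypeSummary"))
  }
  ex <- bundle$exon_index
  hits <- GenomicRanges::findOverlaps(exon_reads, ex,
                                      minoverlap = min_overlap,
                                      ignore.strand = FALSE)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    exon_reads[S4Vectors::queryHits(hits)],
    ex[S4Vectors::subjectHits(hits)], ignore.strand = TRUE))
  gid <- GenomicRanges::mcols(ex)$gene_id[S4Vectors::subjectHits(hits)]
  per <- data.frame(read = S4Vectors::queryHits(hits), gene = gid, ov = ov)
  per <- stats::aggregate(ov ~ read + gene, data = per, FUN = sum)
  # winner per read: max overlap, then lexicographic gene id
  per <- per[order(per$read, -per$ov, per$gene), ]
  win <- per[!duplicated(per$read), ]
  biotype <- bundle$gene_biotype[win$gene]
  tab <- table(biotype)
  counts <- stats::setNames(as.integer(tab), names(tab))
  counts <- sort(counts, decreasing = TRUE)
  structure(list(counts = counts,
                 fractions = counts / length(exon_reads),
                 exon_total = length(exon_reads)),
            class = "BiotypeSummary")
}

#' @export
print.BiotypeSummary <- function(x, ...) {
  cat(sprintf("Biotype summary of %d exon reads\n", x$exon_total))
  for (b in names(x$counts)) {
    cat(sprintf("  %-22s %8d (%5.1f%%)\n", b, x$counts[[b]],
                100 * x$fractions[[b]]))
  }
  invisible(x)
}

#' Filter a count matrix by summed counts across libraries
#'
#' Retains features whose row sum across libraries strictly exceeds
#' `threshold` — the standard expression filter applied before downstream
#' comparisons (e.g. summed counts >20 or >500 across the sample set).
#'
#' @param counts numeric matrix or data frame, features in rows, libraries
#'   in columns.
#' @param threshold keep rows with `rowSums > threshold` (strict).
#' @return the filtered matrix.
#' @export
filter_summed_counts <- function(counts, threshold) {
  counts <- as.matrix(counts)
  counts[rowSums(counts) > threshold, , drop = FALSE]
}
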