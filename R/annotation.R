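#' @importFrom GenomicRanges GRanges GRangesList reduce setdiff strand
#'   start end width seqnames mcols mcols<- findOverlaps countOverlaps
#'   coverage sort
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Construct a stranded genomic interval set
#'
#' Internal coordinates are 0-based half-open everywhere in this package;
#' this helper builds a `GRanges` from such coordinates (GTF/GFF3 parsers
#' convert on ingestion, BED is taken as-is).
#'
#' @param chrom,start,end,strand vectors; `start` 0-based inclusive, `end`
#'   exclusive, strand in `+`, `-` or `*` (either strand).
#' @param ... further metadata columns.
#' @return a `GRanges`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*", ...) {
  if (any(start < 0L) || any(end <= start)) {
    stop("invalid interval: require 0 <= start < end")
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end),
                         strand = strand, ...)
}

# 0-based starts for output
start0 <- function(gr) GenomicRanges::start(gr) - 1L

#' Merge intervals on one chromosome and strand
#'
#' Returns the minimal sorted set of disjoint intervals covering the same
#' bases. Book-ended intervals (end of one equals start of the next, in
#' half-open coordinates) merge.
#'
#' @param ivs a `GRanges`, all on a single chromosome and strand.
#' @return merged, sorted `GRanges`.
#' @export
merge_intervals <- function(ivs) {
  if (length(ivs) > 1L &&
      (length(unique(as.character(GenomicRanges::seqnames(ivs)))) > 1L ||
       length(unique(as.character(GenomicRanges::strand(ivs)))) > 1L)) {
    stop("merge_intervals: intervals span multiple chromosomes or strands")
  }
  GenomicRanges::reduce(GenomicRanges::sort(ivs))
}

#' Strand-aware per-base interval subtraction
#'
#' Removes from `a` every base covered by a same-strand interval of `b`
#' (BEDTools-subtract semantics). Intervals on `*` interact with both
#' strands. Inputs are expected merged (disjoint within a strand).
#'
#' @param a,b `GRanges`.
#' @return merged `GRanges` covering the bases of `a` not in `b`.
#' @export
subtract_intervals <- function(a, b) {
  if (is_unmerged(a) || is_unmerged(b)) {
    stop("subtract_intervals: inputs must be merged (disjoint per strand)")
  }
  GenomicRanges::setdiff(a, b, ignore.strand = FALSE)
}

is_unmerged <- function(gr) {
  length(gr) > 0L &&
    length(GenomicRanges::reduce(gr, ignore.strand = FALSE)) != length(gr)
}

#' Parse a GENCODE-style GTF into transcript models
#'
#' Exon records are grouped under their transcripts; coordinates are
#' converted from 1-based inclusive to 0-based half-open internally (the
#' `GRanges` representation handles this transparently). The biotype is
#' read from `gene_type` or `gene_biotype`, whichever the dialect provides.
#' Feature lines other than `exon` and `transcript` are ignored (their
#' count is reported in the returned object).
#'
#' @param path GTF file path.
#' @return object of class `TranscriptSet`: `transcripts` (data frame with
#'   transcript_id, gene_id, biotype, chrom, strand, span start/end),
#'   `exons` (a `GRangesList` of exon intervals, one element per
#'   transcript), `ignored_features` (named count of skipped feature
#'   types).
#' @export
parse_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- GenomicRanges::mcols(gr)
  if (!"transcript_id" %in% names(md)) {
    stop("parse_gtf: '", path, "' lacks transcript_id attributes")
  }
  biotype <- if ("gene_type" %in% names(md)) md$gene_type
             else if ("gene_biotype" %in% names(md)) md$gene_biotype
             else rep(NA_character_, length(gr))
  keep_types <- c("exon", "transcript")
  ignored <- table(as.character(md$type[!md$type %in% keep_types]))
  ex <- gr[md$type == "exon" & !is.na(md$transcript_id)]
  if (length(ex) == 0L) {
    warning("parse_gtf: no exon records in '", path, "'")
    return(structure(list(
      transcripts = data.frame(transcript_id = character(0)),
      exons = GenomicRanges::GRangesList(),
      ignored_features = ignored), class = "TranscriptSet"))
  }
  if (any(GenomicRanges::end(ex) < GenomicRanges::start(ex))) {
    stop("parse_gtf: exon with end < start")
  }
  ex_md <- GenomicRanges::mcols(ex)
  txid <- as.character(ex_md$transcript_id)
  exl <- S4Vectors::split(granges_bare(ex), txid)
  exl <- GenomicRanges::reduce(exl)          # merged, sorted per transcript
  first <- !duplicated(txid)
  info <- data.frame(
    transcript_id = txid[first],
    gene_id = as.character(ex_md$gene_id[first]),
    biotype = as.character(biotype[md$type == "exon" &
                                   !is.na(md$transcript_id)][first]),
    chrom = as.character(GenomicRanges::seqnames(ex))[first],
    strand = as.character(GenomicRanges::strand(ex))[first],
    stringsAsFactors = FALSE)
  info <- info[match(names(exl), info$transcript_id), , drop = FALSE]
  spans <- range(exl)
  info$span_start <- vapply(seq_along(exl), function(i)
    start0(spans[[i]])[1], numeric(1))
  info$span_end <- vapply(seq_along(exl), function(i)
    GenomicRanges::end(spans[[i]])[1], numeric(1))
  rownames(info) <- NULL
  structure(list(transcripts = info, exons = exl,
                 ignored_features = ignored),
            class = "TranscriptSet")
}

granges_bare <- function(gr) {
  out <- GenomicRanges::granges(gr)
  GenomicRanges::mcols(out) <- NULL
  out
}

#' @export
print.TranscriptSet <- function(x, ...) {
  cat(sprintf("TranscriptSet: %d transcripts, %d genes\n",
              nrow(x$transcripts), length(unique(x$transcripts$gene_id))))
  invisible(x)
}

#' Derive introns of a transcript (span minus merged exons)
#'
#' @param exons `GRanges` of a single transcript's exons (one chromosome
#'   and strand).
#' @return `GRanges` of intronic intervals (possibly empty).
#' @export
derive_introns <- function(exons) {
  ex <- merge_intervals(exons)
  n <- length(ex)
  if (n <= 1L) return(ex[0])
  # span minus merged exons == the gaps between consecutive merged exons
  GenomicRanges::GRanges(
    GenomicRanges::seqnames(ex)[-n],
    IRanges::IRanges(GenomicRanges::end(ex)[-n] + 1L,
                     GenomicRanges::start(ex)[-1L] - 1L),
    strand = GenomicRanges::strand(ex)[-n])
}

#' Derive the non-mature miRNA regions
#'
#' Per-base, strand-aware subtraction of the mature arm intervals from the
#' hairpin precursor (primary transcript) intervals. Reads touching the
#' result (loop, overhangs) are excluded from mature-miRNA counting.
#'
#' @param primary `GRanges` of `miRNA_primary_transcript` features.
#' @param mature `GRanges` of mature `miRNA` features.
#' @return merged `GRanges` of primary-minus-mature regions.
#' @export
derive_nonmature <- function(primary, mature) {
  GenomicRanges::setdiff(GenomicRanges::reduce(granges_bare(primary)),
                         GenomicRanges::reduce(granges_bare(mature)),
                         ignore.strand = FALSE)
}

#' Parse a miRBase-style GFF3 into primary and mature interval sets
#'
#' Recognizes the two feature types `miRNA_primary_transcript` (hairpin
#' precursors) and `miRNA` (mature arms); everything else is ignored with a
#' count. Interval names are taken from the `Name` attribute, falling back
#' to `ID`.
#'
#' @param path GFF3 file path.
#' @return list with `primary` and `mature` (named `GRanges`) and
#'   `ignored_features` (named count).
#' @export
parse_mirna_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- GenomicRanges::mcols(gr)
  type <- as.character(md$type)
  nm <- if ("Name" %in% names(md)) as.character(md$Name) else NA_character_
  id <- if ("ID" %in% names(md)) as.character(md$ID) else NA_character_
  labels <- ifelse(is.na(nm) | nm == "", id, nm)
  pick <- function(what) {
    sel <- type == what
    out <- granges_bare(gr[sel])
    names(out) <- labels[sel]
    GenomicRanges::mcols(out)$accession <- id[sel]
    out
  }
  ignored <- table(type[!type %in% c("miRNA_primary_transcript", "miRNA")])
  list(primary = pick("miRNA_primary_transcript"),
       mature = pick("miRNA"),
       ignored_features = ignored)
}

#' Parse a BED3/BED6 file into a stranded interval set
#'
#' BED is already 0-based half-open. Records without a strand column (or
#' with strand `.`) are treated as matching either strand, since tRNA and
#' repeat tracks frequently omit strand and a strict same-strand rule would
#' silently drop those layers.
#'
#' @param path BED file path.
#' @return `GRanges` (strand `*` for strandless records; `name` metadata
#'   column when present).
#' @export
parse_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("malformed BED '", path, "': ",
                                          conditionMessage(e)))
  gr
}

#' Write an interval set to BED6
#'
#' Deterministic plain-text output: 0-based half-open coordinates, name
#' from `names()` or the `name` column (`.` when absent), score 0, strand
#' (`.` for `*`).
#'
#' @param gr `GRanges`.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  nm <- names(gr)
  if (is.null(nm) && "name" %in% names(GenomicRanges::mcols(gr))) {
    nm <- GenomicRanges::mcols(gr)$name
  }
  if (is.null(nm)) nm <- rep(".", length(gr))
  nm[is.na(nm) | nm == ""] <- "."
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   as.character(GenomicRanges::seqnames(gr)),
                   start0(gr), GenomicRanges::end(gr), nm, strand)
  writeLines(lines, path)
  invisible(path)
}

#' Assemble the layered annotation bundle
#'
#' Builds the strand-aware feature layers used for hierarchical read
#' assignment: exons (merged per gene, with biotype), introns (per
#' transcript, span minus merged exons, unioned), tRNA and repeat
#' intervals, and the miRNA primary / mature / derived non-mature sets.
#'
#' @param gtf path to a GENCODE-style GTF, or a `TranscriptSet` from
#'   [parse_gtf()].
#' @param trna path to a tRNA BED or GTF (optional).
#' @param repeats path to a RepeatMasker-style BED (optional).
#' @param mirna_gff3 path to a miRBase-style GFF3 (optional).
#' @return object of class `AnnotationBundle` with components
#'   `exon_index` (per-gene merged exons, metadata `gene_id`, `biotype`),
#'   `intron_index`, `trna_index`, `repeat_index`, `gene_biotype` (named
#'   character vector), `transcripts` (the `TranscriptSet`),
#'   `mirna_primary`, `mirna_mature`, `mirna_nonmature`.
#' @export
build_annotation_bundle <- function(gtf, trna = NULL, repeats = NULL,
                                    mirna_gff3 = NULL) {
  txs <- if (inherits(gtf, "TranscriptSet")) gtf else parse_gtf(gtf)
  info <- txs$transcripts

  # merged exon union per gene, carrying gene_id + biotype
  flat <- unlist(txs$exons, use.names = FALSE)
  gene_of_tx <- stats::setNames(info$gene_id, info$transcript_id)
  gene_ids <- rep(gene_of_tx[names(txs$exons)],
                  S4Vectors::elementNROWS(txs$exons))
  by_gene <- GenomicRanges::reduce(S4Vectors::split(flat, gene_ids))
  exon_index <- unlist(by_gene, use.names = FALSE)
  GenomicRanges::mcols(exon_index)$gene_id <-
    rep(names(by_gene), S4Vectors::elementNROWS(by_gene))
  biotype_map <- tapply(info$biotype, info$gene_id, function(b) b[1])
  biotype_map <- stats::setNames(as.character(biotype_map),
                                 names(biotype_map))
  GenomicRanges::mcols(exon_index)$biotype <-
    unname(biotype_map[GenomicRanges::mcols(exon_index)$gene_id])

  # intron union: per transcript, span minus merged exons
  intr <- lapply(seq_along(txs$exons), function(i) derive_introns(txs$exons[[i]]))
  intron_index <- if (length(intr)) {
    GenomicRanges::reduce(do.call(c, intr))
  } else GenomicRanges::GRanges()

  trna_index <- load_layer(trna)
  repeat_index <- load_layer(repeats)

  mir <- if (!is.null(mirna_gff3)) {
    if (is.list(mirna_gff3) && !is.character(mirna_gff3)) mirna_gff3
    else parse_mirna_gff3(mirna_gff3)
  } else list(primary = GenomicRanges::GRanges(),
              mature = GenomicRanges::GRanges())

  structure(list(
    exon_index = exon_index,
    intron_index = intron_index,
    trna_index = trna_index,
    repeat_index = repeat_index,
    gene_biotype = biotype_map,
    transcripts = txs,
    mirna_primary = mir$primary,
    mirna_mature = mir$mature,
    mirna_nonmature = derive_nonmature(mir$primary, mir$mature)
  ), class = "AnnotationBundle")
}

load_layer <- function(x) {
  if (is.null(x)) return(GenomicRanges::GRanges())
  if (inherits(x, "GRanges")) return(x)
  if (grepl("\\.gtf(\\.gz)?$", x)) {
    gr <- rtracklayer::import(x, format = "gtf")
    return(granges_bare(gr[GenomicRanges::mcols(gr)$type %in%
                             c("exon", "gene", "tRNA")]))
  }
  parse_bed(x)
}

#' @export
print.AnnotationBundle <- function(x, ...) {
  cat("AnnotationBundle\n")
  cat(sprintf("  exon intervals:   %6d (%d genes)\n", length(x$exon_index),
              length(unique(GenomicRanges::mcols(x$exon_index)$gene_id))))
  cat(sprintf("  intron intervals: %6d\n", length(x$intron_index)))
  cat(sprintf("  tRNA intervals:   %6d\n", length(x$trna_index)))
  cat(sprintf("  repeat intervals: %6d\n", length(x$repeat_index)))
  cat(sprintf("  miRNA: %d primary, %d mature, %d non-mature\n",
              length(x$mirna_primary), length(x$mirna_mature),
              length(x$mirna_nonmature)))
  invisible(x)
}

#' Serialize an annotation bundle to a directory of BED files
#'
#' Writes one BED per layer plus a JSON manifest carrying the gene biotype
#' map. Round-tripping through [read_annotation_bundle()] preserves
#' per-base occupancy of every layer.
#'
#' @param bundle an `AnnotationBundle`.
#' @param dir output directory (created if needed).
#' @export
write_annotation_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ex <- bundle$exon_index
  names(ex) <- GenomicRanges::mcols(ex)$gene_id
  write_bed(ex, file.path(dir, "exon.bed"))
  write_bed(bundle$intron_index, file.path(dir, "intron.bed"))
  write_bed(bundle$trna_index, file.path(dir, "trna.bed"))
  write_bed(bundle$repeat_index, file.path(dir, "repeat.bed"))
  write_bed(bundle$mirna_primary, file.path(dir, "mirna_primary.bed"))
  write_bed(bundle$mirna_mature, file.path(dir, "mirna_mature.bed"))
  write_bed(bundle$mirna_nonmature, file.path(dir, "mirna_nonmature.bed"))
  jsonlite::write_json(
    list(layers = c("exon", "intron", "trna", "repeat", "mirna_primary",
                    "mirna_mature", "mirna_nonmature"),
         gene_biotype = as.list(bundle$gene_biotype)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read an annotation bundle serialized by [write_annotation_bundle()]
#'
#' @param dir directory written by [write_annotation_bundle()].
#' @return an `AnnotationBundle` (without transcript models, which BED does
#'   not carry; counting and assignment layers are fully restored).
#' @export
read_annotation_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  rd <- function(layer) {
    p <- file.path(dir, paste0(layer, ".bed"))
    if (file.exists(p) && file.size(p) > 0) parse_bed(p)
    else GenomicRanges::GRanges()
  }
  ex <- rd("exon")
  biotype_map <- unlist(manifest$gene_biotype)
  gid <- GenomicRanges::mcols(ex)$name
  GenomicRanges::mcols(ex)$gene_id <- gid
  GenomicRanges::mcols(ex)$biotype <- unname(biotype_map[gid])
  prim <- rd("mirna_primary"); mat <- rd("mirna_mature")
  name_up <- function(g) {
    if ("name" %in% names(GenomicRanges::mcols(g))) {
      names(g) <- GenomicRanges::mcols(g)$name
      GenomicRanges::mcols(g)$accession <- GenomicRanges::mcols(g)$name
    }
    g
  }
  structure(list(
    exon_index = ex,
    intron_index = rd("intron"),
    trna_index = rd("trna"),
    repeat_index = rd("repeat"),
    gene_biotype = biotype_map,
    transcripts = NULL,
    mirna_primary = name_up(prim),
    mirna_mature = name_up(mat),
    mirna_nonmature = rd("mirna_nonmature")
  ), class = "AnnotationBundle")
}
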