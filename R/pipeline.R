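#' Run the full pipeline on one library
#'
#' Orchestrates the stages end to end: (optionally) simulate a library,
#' preprocess the FASTQ (tail selection + clipping), take alignments from
#' a BAM/BED file or from the simulator's ground truth, then assign
#' categories, count genes, summarize biotypes, quantify mature miRNAs and
#' emit QC outputs. A JSON manifest records parameters, input hashes and
#' per-stage summary statistics.
#'
#' When alignments come from the simulator's truth records, they are
#' restricted to the reads that survived preprocessing, mimicking the real
#' flow where only clipped inserts reach the aligner.
#'
#' @param out_dir output directory.
#' @param bundle an `AnnotationBundle`, or a directory serialized by
#'   [write_annotation_bundle()].
#' @param fastq input FASTQ path; `NULL` when simulating.
#' @param alignments alignment BAM/BED path, a `GRanges`, or `NULL` to use
#'   the simulated truth.
#' @param sim a `SimConfig` to simulate the input library, or `NULL` for
#'   real input.
#' @param reference a `ToyReference` (required when `sim` is given;
#'   built from `sim$seed` if missing).
#' @param library_id library name used in reports.
#' @param min_tail,min_insert,max_interruptions preprocessing parameters
#'   (see [detect_tail()]).
#' @param strand_mode gene-counting strand mode (see [count_genes()]).
#' @return a list of class `PipelineResult` with per-stage objects
#'   (`preprocess`, `categories`, `gene_counts`, `biotypes`, `mature`,
#'   `gene_body`, `tracks`, `report`) and the manifest.
#' @export
run_pipeline <- function(out_dir, bundle = NULL, fastq = NULL,
                         alignments = NULL, sim = NULL, reference = NULL,
                         library_id = "lib1", min_tail = 9L,
                         min_insert = 18L, max_interruptions = 0L,
                         strand_mode = "forward") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(library_id = library_id,
                   parameters = list(min_tail = min_tail,
                                     min_insert = min_insert,
                                     max_interruptions = max_interruptions,
                                     strand_mode = strand_mode),
                   stages = list())
  simlib <- NULL
  if (!is.null(sim)) {
    if (is.null(reference)) reference <- build_toy_reference(sim$seed)
    bundle <- reference$bundle
    simlib <- simulate_library(reference, sim)
    paths <- write_sim_library(simlib, out_dir, prefix = library_id)
    fastq <- paths[["fastq"]]
    manifest$parameters$sim <- unclass(sim)
    manifest$stages$simulate <- list(
      reads = nrow(simlib$reads),
      molecules = length(unique(simlib$truth$molecule_id)))
  }
  if (is.null(bundle)) stop("run_pipeline: no annotation bundle")
  if (is.character(bundle)) bundle <- read_annotation_bundle(bundle)
  if (is.null(fastq) || !file.exists(fastq)) {
    stop("run_pipeline: missing FASTQ input")
  }
  manifest$inputs <- list(fastq = unname(tools::md5sum(fastq)))

  clipped <- file.path(out_dir, paste0(library_id, ".clipped.fastq.gz"))
  pp <- process_fastq(fastq, clipped, min_tail = min_tail,
                      min_insert = min_insert,
                      max_interruptions = max_interruptions)
  manifest$stages$preprocess <- list(reads_in = pp$reads_in,
                                     reads_with_tail = pp$reads_with_tail,
                                     reads_out = pp$reads_out)

  aln <- if (is.null(alignments)) {
    if (is.null(simlib)) stop("run_pipeline: no alignments and no simulation")
    gr <- emit_truth_alignments(simlib)
    gr[GenomicRanges::mcols(gr)$read_id %in% pp$kept_ids]
  } else if (inherits(alignments, "GRanges")) {
    alignments
  } else {
    if (!file.exists(alignments)) {
      stop("run_pipeline: missing alignment input '", alignments, "'")
    }
    read_alignments(alignments)
  }
  manifest$stages$align <- list(aligned = length(aln))

  cats <- count_categories(aln, bundle)
  genes <- count_genes(aln, bundle, strand_mode = strand_mode)
  bio <- summarize_biotypes(aln, bundle)
  mature <- quantify_mature_mirna(aln, bundle)
  utils::write.table(
    data.frame(gene_id = names(genes), count = as.integer(genes)),
    file.path(out_dir, paste0(library_id, ".gene_counts.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(mature_id = names(mature$counts),
               count = unname(mature$counts)),
    file.path(out_dir, paste0(library_id, ".mature_counts.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)

  gb <- if (!is.null(bundle$transcripts)) {
    gene_body_coverage(aln, bundle$transcripts)
  }
  tracks <- if (length(aln) > 0) rpm_tracks(aln)
  if (!is.null(tracks)) {
    write_bedgraph(tracks, file.path(out_dir, library_id))
  }
  report <- composition_report(
    library_id, preprocess = pp, categories = cats, biotypes = bio,
    mature = mature,
    path = file.path(out_dir, paste0(library_id, ".report.json")))
  manifest$stages$assign <- list(
    aligned_total = cats$aligned_total,
    categories = unclass(cats)[.CATEGORIES])
  manifest$stages$mirna <- list(removed = mature$removed_reads,
                                mature_total = sum(mature$counts))
  manifest_path <- file.path(out_dir, paste0(library_id, ".manifest.json"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  structure(list(preprocess = pp, alignments = aln, categories = cats,
                 gene_counts = genes, biotypes = bio, mature = mature,
                 gene_body = gb, tracks = tracks, report = report,
                 manifest = manifest, out_dir = out_dir),
            class = "PipelineResult")
}

#' @export
print.PipelineResult <- function(x, ...) {
  print(x$report)
  invisible(x)
}
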