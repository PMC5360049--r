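#' Simulation configuration for a polyadenylation-chemistry library
#'
#' Collects the generative parameters of the simulator. The model mirrors
#' the library chemistry: every captured RNA 3' end receives a poly(A)
#' tail (by poly(A) polymerase for non-preadenylated classes), an anchored
#' oligo-dT primer fixes the encoded tail length, reverse transcription
#' starts at the tail/insert junction and terminates stochastically while
#' extending 5'-ward (producing the 3' coverage bias of long RNAs), and
#' PCR preamplification duplicates molecules with lognormal efficiency
#' spread.
#'
#' @param seed integer seed; all randomness derives from it.
#' @param n_reads number of captured molecules to draw.
#' @param read_length sequencing read length in bases (default 50).
#' @param class_mix named fractions over RNA classes `miRNA`, `snoRNA`,
#'   `tRNA`, `rRNA`, `repeat_derived`, `mRNA`, `intronic`, `intergenic`;
#'   must sum to 1.
#' @param tail_length_dist tail-length distribution: `list(dist =
#'   "constant", value = 20)` (default, the length fixed by a T20V
#'   anchored primer), or `dist = "poisson"` (`lambda`), `"uniform"`
#'   (`min`, `max`), `"geometric"` (`p`, shifted by 1).
#' @param rt_dropoff_p per-base reverse-transcription termination
#'   probability in (0,1); insert lengths of long RNAs are geometric with
#'   mean `1/rt_dropoff_p`, anchored at the 3' end.
#' @param amp_bias_sigma lognormal sigma of per-molecule amplification
#'   efficiency; 0 disables duplication.
#' @param error_rate per-base substitution probability.
#' @param size_window `c(min_insert, max_insert)`: molecules whose insert
#'   falls outside are lost to size selection.
#' @param pap_enabled poly(A) polymerase present; when `FALSE` only
#'   mRNA-class (pre-polyadenylated) molecules yield reads.
#' @param rt_enabled reverse transcriptase present; when `FALSE` the
#'   library is empty.
#' @return a list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L, n_reads = 10000L, read_length = 50L,
                       class_mix = c(miRNA = 0.30, snoRNA = 0.10,
                                     tRNA = 0.15, rRNA = 0.15,
                                     repeat_derived = 0.05, mRNA = 0.15,
                                     intronic = 0.05, intergenic = 0.05),
                       tail_length_dist = list(dist = "constant", value = 20L),
                       rt_dropoff_p = 0.01, amp_bias_sigma = 0.25,
                       error_rate = 0.001, size_window = c(18L, 1000L),
                       pap_enabled = TRUE, rt_enabled = TRUE) {
  if (abs(sum(class_mix) - 1) > 1e-6) stop("class_mix must sum to 1")
  if (any(class_mix < 0)) stop("class_mix fractions must be >= 0")
  if (rt_dropoff_p <= 0 || rt_dropoff_p >= 1) {
    stop("rt_dropoff_p must be in (0,1)")
  }
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0,1]")
  if (size_window[1] > size_window[2]) stop("empty size_window")
  structure(list(seed = as.integer(seed), n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 class_mix = class_mix, tail_length_dist = tail_length_dist,
                 rt_dropoff_p = rt_dropoff_p,
                 amp_bias_sigma = amp_bias_sigma, error_rate = error_rate,
                 size_window = as.integer(size_window),
                 pap_enabled = isTRUE(pap_enabled),
                 rt_enabled = isTRUE(rt_enabled)),
            class = "SimConfig")
}

# ---------------------------------------------------------------------------
# Toy reference layout. Coordinates are 0-based half-open, fixed by design;
# only the base sequence is random. The layout deliberately includes an
# exon-over-repeat overlap and an antisense gene pair for priority and
# strandedness testing, and keeps [70000, 95000) on toyA annotation-free as
# intergenic source space.
# ---------------------------------------------------------------------------

toy_layout <- function() {
  ex <- function(...) list(...)
  genes <- list(
    list(id = "GENE1", chrom = "toyA", strand = "+", biotype = "protein_coding",
         exons = ex(c(1000, 2000), c(4000, 5500), c(7500, 9000))),
    list(id = "GENE2", chrom = "toyA", strand = "-", biotype = "protein_coding",
         exons = ex(c(12000, 13500), c(16000, 17000), c(19000, 20000))),
    list(id = "GENE3", chrom = "toyA", strand = "+", biotype = "protein_coding",
         exons = ex(c(22000, 24000), c(26000, 27000), c(28500, 30000))),
    list(id = "GENE4", chrom = "toyA", strand = "+", biotype = "protein_coding",
         exons = ex(c(32000, 36000))),
    list(id = "GENE5", chrom = "toyA", strand = "-", biotype = "antisense",
         exons = ex(c(33000, 35000))),
    list(id = "GENE6", chrom = "toyB", strand = "+", biotype = "protein_coding",
         exons = ex(c(1000, 3000))),
    # short histone-like mRNAs: bodies comparable to typical RT processivity,
    # so gene-body profiles retain resolution across drop-off rates
    list(id = "GENE7", chrom = "toyA", strand = "+", biotype = "protein_coding",
         exons = ex(c(64000, 64500))),
    list(id = "GENE8", chrom = "toyA", strand = "-", biotype = "protein_coding",
         exons = ex(c(65000, 65400), c(65600, 66000))),
    list(id = "SNORD1", chrom = "toyA", strand = "+", biotype = "snoRNA",
         exons = ex(c(40000, 40120))),
    list(id = "SNORD2", chrom = "toyA", strand = "-", biotype = "snoRNA",
         exons = ex(c(40500, 40610))),
    list(id = "SNORD3", chrom = "toyA", strand = "+", biotype = "snoRNA",
         exons = ex(c(41000, 41130))),
    list(id = "SNORD4", chrom = "toyA", strand = "+", biotype = "snoRNA",
         exons = ex(c(41500, 41600))),
    list(id = "RNA45S", chrom = "toyA", strand = "+", biotype = "rRNA",
         exons = ex(c(44000, 45900))),
    list(id = "MIRG1", chrom = "toyA", strand = "+", biotype = "miRNA",
         exons = ex(c(50000, 50084))),
    list(id = "MIRG2", chrom = "toyA", strand = "-", biotype = "miRNA",
         exons = ex(c(51000, 51090))),
    list(id = "MIRG3", chrom = "toyA", strand = "+", biotype = "miRNA",
         exons = ex(c(52000, 52080))),
    list(id = "MIRG4", chrom = "toyA", strand = "-", biotype = "miRNA",
         exons = ex(c(53000, 53086))))
  mirna <- list(
    list(primary_id = "MI0001", primary_name = "toy-mir-1", chrom = "toyA",
         strand = "+", primary = c(50000, 50084),
         arms = list(list(id = "MIMAT0001", name = "toy-miR-1-5p",
                          iv = c(50008, 50030)),
                     list(id = "MIMAT0002", name = "toy-miR-1-3p",
                          iv = c(50052, 50074)))),
    list(primary_id = "MI0002", primary_name = "toy-mir-2", chrom = "toyA",
         strand = "-", primary = c(51000, 51090),
         arms = list(list(id = "MIMAT0003", name = "toy-miR-2-3p",
                          iv = c(51010, 51032)),
                     list(id = "MIMAT0004", name = "toy-miR-2-5p",
                          iv = c(51058, 51080)))),
    list(primary_id = "MI0003", primary_name = "toy-mir-3", chrom = "toyA",
         strand = "+", primary = c(52000, 52080),
         arms = list(list(id = "MIMAT0005", name = "toy-miR-3-5p",
                          iv = c(52006, 52028)),
                     list(id = "MIMAT0006", name = "toy-miR-3-3p",
                          iv = c(52050, 52072)))),
    list(primary_id = "MI0004", primary_name = "toy-mir-4", chrom = "toyA",
         strand = "-", primary = c(53000, 53086),
         arms = list(list(id = "MIMAT0007", name = "toy-miR-4-3p",
                          iv = c(53008, 53030)),
                     list(id = "MIMAT0008", name = "toy-miR-4-5p",
                          iv = c(53055, 53077)))))
  trna <- data.frame(
    chrom = "toyA", start = c(56000, 56500, 57000, 57500),
    end = c(56072, 56572, 57072, 57572),
    name = paste0("tRNA-", 1:4),
    strand = c("+", "-", ".", "+"),
    sim_strand = c("+", "-", "-", "+"),  # molecule strand used by simulator
    stringsAsFactors = FALSE)
  repeats <- data.frame(
    chrom = c("toyA", "toyA", "toyA", "toyA", "toyA", "toyB"),
    start = c(22500, 60000, 61000, 62000, 63000, 3500),
    end = c(23000, 60500, 61800, 62300, 63400, 3800),
    name = c("REP_under_exon", "REP1", "REP2", "REP3", "REP4", "REP5"),
    strand = c("+", "+", "-", ".", "+", "+"),
    stringsAsFactors = FALSE)
  list(genes = genes, mirna = mirna, trna = trna, repeats = repeats,
       chrom_len = c(toyA = 100000L, toyB = 5000L),
       intergenic = data.frame(chrom = "toyA", start = 70000L, end = 95000L))
}

#' Build the bundled toy reference (genome + annotation files)
#'
#' Writes a deterministic small genome (two chromosomes, ~105 kb) and its
#' annotation: a GENCODE-style GTF with multi-exon protein-coding genes,
#' snoRNA/rRNA/miRNA genes and an antisense gene pair; a miRBase-style
#' GFF3 with hairpin precursors and mature arms; a tRNA BED (including a
#' strandless record); and a RepeatMasker-style BED including a repeat
#' lying under an exon (priority test case). The base sequence is random
#' under `seed`; feature coordinates are fixed. The base preceding each
#' annotated molecule 3' end is forced non-A so that clipping an appended
#' tail recovers the insert exactly.
#'
#' @param seed integer seed for the base sequence.
#' @param dir output directory (default: a fresh temporary directory).
#' @return list of class `ToyReference`: `dir`, file paths (`genome`,
#'   `gtf`, `trna`, `repeats`, `mirna_gff3`), the parsed
#'   `bundle` (an `AnnotationBundle`), the genome as a
#'   `Biostrings::DNAStringSet`, and internal source-molecule tables used
#'   by [simulate_library()].
#' @export
build_toy_reference <- function(seed = 1L, dir = tempfile("toyref")) {
  layout <- toy_layout()
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  chroms <- lapply(layout$chrom_len, function(n)
    sample(c("A", "C", "G", "T"), n, replace = TRUE))

  # force the transcribed 3'-terminal base of every anchored molecule to C
  fix3 <- function(chrom, start, end, strand) {
    if (strand == "-") chroms[[chrom]][start + 1L] <<- "G"
    else chroms[[chrom]][end] <<- "C"
  }
  for (g in layout$genes) {
    last <- g$exons[[length(g$exons)]]
    first <- g$exons[[1L]]
    if (g$strand == "+") fix3(g$chrom, last[1], last[2], "+")
    else fix3(g$chrom, first[1], first[2], "-")
  }
  for (m in layout$mirna) for (a in m$arms) {
    fix3(m$chrom, a$iv[1], a$iv[2], m$strand)
  }
  for (i in seq_len(nrow(layout$trna))) {
    fix3(layout$trna$chrom[i], layout$trna$start[i], layout$trna$end[i],
         layout$trna$sim_strand[i])
  }

  genome <- Biostrings::DNAStringSet(vapply(chroms, paste, "", collapse = ""))
  names(genome) <- names(layout$chrom_len)
  paths <- list(genome = file.path(dir, "genome.fa"),
                gtf = file.path(dir, "genes.gtf"),
                trna = file.path(dir, "trna.bed"),
                repeats = file.path(dir, "repeats.bed"),
                mirna_gff3 = file.path(dir, "mirna.gff3"))
  Biostrings::writeXStringSet(genome, paths$genome)
  write_toy_gtf(layout$genes, paths$gtf)
  utils::write.table(
    layout$trna[, c("chrom", "start", "end", "name")] |>
      cbind(score = 0, strand = layout$trna$strand),
    paths$trna, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  utils::write.table(
    layout$repeats[, c("chrom", "start", "end", "name")] |>
      cbind(score = 0, strand = layout$repeats$strand),
    paths$repeats, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  write_toy_mirna_gff3(layout$mirna, paths$mirna_gff3)

  bundle <- build_annotation_bundle(paths$gtf, trna = paths$trna,
                                    repeats = paths$repeats,
                                    mirna_gff3 = paths$mirna_gff3)
  structure(list(dir = dir, files = paths, bundle = bundle,
                 genome = genome, layout = layout,
                 sources = build_sources(layout, chroms)),
            class = "ToyReference")
}

write_toy_gtf <- function(genes, path) {
  lines <- character(0)
  for (g in genes) {
    span <- c(min(vapply(g$exons, `[`, 0, 1)),
              max(vapply(g$exons, `[`, 0, 2)))
    attr_tx <- sprintf(
      'gene_id "%s"; transcript_id "%s.t1"; gene_type "%s"; gene_name "%s";',
      g$id, g$id, g$biotype, g$id)
    lines <- c(lines, sprintf("%s\ttoy\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                              g$chrom, span[1] + 1L, span[2], g$strand,
                              attr_tx))
    for (e in g$exons) {
      lines <- c(lines, sprintf("%s\ttoy\texon\t%d\t%d\t.\t%s\t.\t%s",
                                g$chrom, e[1] + 1L, e[2], g$strand, attr_tx))
    }
  }
  writeLines(lines, path)
}

write_toy_mirna_gff3 <- function(mirna, path) {
  lines <- "##gff-version 3"
  for (m in mirna) {
    lines <- c(lines, sprintf(
      "%s\t.\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
      m$chrom, m$primary[1] + 1L, m$primary[2], m$strand, m$primary_id,
      m$primary_name))
    for (a in m$arms) {
      lines <- c(lines, sprintf(
        "%s\t.\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;Derives_from=%s",
        m$chrom, a$iv[1] + 1L, a$iv[2], m$strand, a$id, a$name,
        m$primary_id))
    }
  }
  writeLines(lines, path)
}

# Precompute source molecules for the simulator.
# Anchored molecules (miRNA arms, snoRNA, tRNA, rRNA, mRNA) carry the full
# transcript-oriented sequence and the genomic endpoints of each transcript
# position; random-end classes (intronic, repeat_derived, intergenic) carry
# parent intervals from which per-read 3' ends are drawn.
build_sources <- function(layout, chroms) {
  revcomp <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  tx_seq <- function(chrom, exons, strand) {
    s <- paste(vapply(exons, function(e)
      paste(chroms[[chrom]][(e[1] + 1L):e[2]], collapse = ""), ""),
      collapse = "")
    if (strand == "-") revcomp(s) else s
  }
  tx_pos <- function(exons, strand) {
    p <- unlist(lapply(exons, function(e) e[1]:(e[2] - 1L)))
    if (strand == "-") rev(p) else p
  }
  anchored <- function(id, chrom, strand, exons, class) {
    list(id = id, class = class, chrom = chrom, strand = strand,
         seq = tx_seq(chrom, exons, strand), pos = tx_pos(exons, strand))
  }
  src <- list(miRNA = list(), snoRNA = list(), tRNA = list(), rRNA = list(),
              mRNA = list())
  for (g in layout$genes) {
    if (g$biotype %in% c("protein_coding", "antisense")) {
      src$mRNA <- c(src$mRNA, list(anchored(g$id, g$chrom, g$strand,
                                            g$exons, "mRNA")))
    } else if (g$biotype == "snoRNA") {
      src$snoRNA <- c(src$snoRNA, list(anchored(g$id, g$chrom, g$strand,
                                                g$exons, "snoRNA")))
    } else if (g$biotype == "rRNA") {
      src$rRNA <- c(src$rRNA, list(anchored(g$id, g$chrom, g$strand,
                                            g$exons, "rRNA")))
    }
  }
  for (m in layout$mirna) for (a in m$arms) {
    src$miRNA <- c(src$miRNA, list(anchored(
      a$name, m$chrom, m$strand, list(a$iv), "miRNA")))
  }
  for (i in seq_len(nrow(layout$trna))) {
    src$tRNA <- c(src$tRNA, list(anchored(
      layout$trna$name[i], layout$trna$chrom[i], layout$trna$sim_strand[i],
      list(c(layout$trna$start[i], layout$trna$end[i])), "tRNA")))
  }
  # introns (per transcript) as random-end parents
  introns <- list()
  for (g in layout$genes) {
    if (length(g$exons) < 2L) next
    for (k in seq_len(length(g$exons) - 1L)) {
      introns <- c(introns, list(list(
        id = paste0(g$id, ".intron", k), chrom = g$chrom, strand = g$strand,
        start = g$exons[[k]][2], end = g$exons[[k + 1L]][1])))
    }
  }
  reps <- layout$repeats[layout$repeats$name != "REP_under_exon", ]
  repeat_parents <- lapply(seq_len(nrow(reps)), function(i) list(
    id = reps$name[i], chrom = reps$chrom[i],
    strand = if (reps$strand[i] == ".") "*" else reps$strand[i],
    start = reps$start[i], end = reps$end[i]))
  inter <- layout$intergenic
  intergenic_parents <- lapply(seq_len(nrow(inter)), function(i) list(
    id = paste0("intergenic", i), chrom = inter$chrom[i], strand = "*",
    start = inter$start[i], end = inter$end[i]))
  list(anchored = src,
       random_end = list(intronic = introns, repeat_derived = repeat_parents,
                         intergenic = intergenic_parents),
       chroms = chroms)
}

draw_tails <- function(n, d) {
  switch(d$dist,
         constant = rep(as.integer(d$value), n),
         poisson = stats::rpois(n, d$lambda),
         uniform = sample(seq(d$min, d$max), n, replace = TRUE),
         geometric = 1L + stats::rgeom(n, d$p),
         stop("unknown tail_length_dist: ", d$dist))
}

.CLASS_CATEGORY <- c(miRNA = "exon", snoRNA = "exon", rRNA = "exon",
                     mRNA = "exon", tRNA = "trna", intronic = "intron",
                     repeat_derived = "repeat", intergenic = "unannotated")

#' Simulate a poly(A)-tailed sequencing library with ground truth
#'
#' Generates reads according to the library chemistry: a molecule's RNA
#' class and source are drawn from the configured mix; short RNAs (miRNA
#' mature arms, snoRNA, tRNA) are captured full-length, long RNAs (mRNA,
#' rRNA) yield 3'-anchored inserts with geometric length (per-base RT
#' termination `rt_dropoff_p`); intron-, repeat- and intergenic-derived
#' fragments get a uniform 3' end inside their parent interval and a
#' geometric extension. A poly(A) tail of drawn length is appended, size
#' selection is applied to the insert, molecules are duplicated with
#' lognormal amplification weights, substitution errors are applied, and
#' the read is truncated to the read length. Without poly(A) polymerase
#' (`pap_enabled = FALSE`) only pre-polyadenylated mRNA-class molecules
#' survive; without reverse transcriptase nothing does.
#'
#' Truth records carry, per emitted read, the genomic footprint a perfect
#' aligner would report for the clipped insert (the 5'-most
#' `min(insert, read_length)` insert bases; for spliced inserts the
#' reference span including introns), the source molecule, RNA class, the
#' category the bundled annotation implies, and the drawn tail length.
#'
#' @param reference a `ToyReference` from [build_toy_reference()].
#' @param config a `SimConfig` from [sim_config()].
#' @return object of class `SimLibrary`: `reads` (data frame `read_id`,
#'   `sequence`, `qualities`), `truth` (data frame `read_id`,
#'   `molecule_id`, `class`, `source_id`, `chrom`, `start`, `end`,
#'   `strand`, `insert_length`, `tail_length`, `category`), `config`.
#' @export
simulate_library <- function(reference, config = sim_config()) {
  stopifnot(inherits(reference, "ToyReference"), inherits(config, "SimConfig"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  empty <- function() structure(list(
    reads = data.frame(read_id = character(0), sequence = character(0),
                       qualities = character(0)),
    truth = data.frame(read_id = character(0), molecule_id = character(0),
                       class = character(0), source_id = character(0),
                       chrom = character(0), start = integer(0),
                       end = integer(0), strand = character(0),
                       insert_length = integer(0), tail_length = integer(0),
                       category = character(0)),
    config = config), class = "SimLibrary")
  if (!config$rt_enabled || config$n_reads == 0L) return(empty())

  n <- config$n_reads
  mix <- config$class_mix[config$class_mix > 0]
  classes <- sample(names(mix), n, replace = TRUE, prob = mix)
  geomL <- 1L + stats::rgeom(n, config$rt_dropoff_p)
  tails <- draw_tails(n, config$tail_length_dist)
  amp <- stats::rlnorm(n, 0, max(config$amp_bias_sigma, 1e-12))
  copies <- pmax(1L, as.integer(round(amp)))
  u_src <- stats::runif(n)      # source choice within class
  u_end <- stats::runif(n)      # 3'-end position for random-end classes
  u_str <- stats::runif(n)      # strand for strandless parents

  src <- reference$sources
  chroms <- src$chroms
  revcomp_chr <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  seqs <- character(n); chrom <- character(n); strand <- character(n)
  s0 <- integer(n); e0 <- integer(n); source_id <- character(n)
  ins_len <- integer(n)
  RL <- config$read_length

  for (i in seq_len(n)) {
    cl <- classes[i]
    if (cl %in% names(src$anchored)) {
      pool <- src$anchored[[cl]]
      m <- pool[[1L + floor(u_src[i] * length(pool))]]
      full <- nchar(m$seq)
      L <- if (cl %in% c("mRNA", "rRNA")) min(geomL[i], full) else full
      ins_len[i] <- L
      seqs[i] <- substr(m$seq, full - L + 1L, full)
      sl <- min(L, RL)          # sequenced (alignable) part: 5' side of insert
      p1 <- m$pos[full - L + 1L]; p2 <- m$pos[full - L + sl]
      s0[i] <- min(p1, p2); e0[i] <- max(p1, p2) + 1L
      chrom[i] <- m$chrom; strand[i] <- m$strand; source_id[i] <- m$id
    } else {
      pool <- src$random_end[[cl]]
      m <- pool[[1L + floor(u_src[i] * length(pool))]]
      st <- if (m$strand == "*") {
        if (u_str[i] < 0.5) "+" else "-"
      } else m$strand
      W <- m$end - m$start
      # 3' end uniform within the parent; geometric 5'-ward extension
      if (st == "+") {
        end3 <- m$start + 1L + floor(u_end[i] * W)      # exclusive end
        L <- min(geomL[i], end3 - m$start)
        iv <- c(end3 - L, end3)
      } else {
        end3 <- m$start + floor(u_end[i] * W)           # inclusive 0-based
        L <- min(geomL[i], m$end - end3)
        iv <- c(end3, end3 + L)
      }
      ins_len[i] <- L
      raw <- paste(chroms[[m$chrom]][(iv[1] + 1L):iv[2]], collapse = "")
      seqs[i] <- if (st == "-") {
        paste(rev(revcomp_chr[strsplit(raw, "")[[1L]]]), collapse = "")
      } else raw
      sl <- min(L, RL)
      if (st == "+") { s0[i] <- iv[2] - L; e0[i] <- iv[2] - L + sl }
      else { s0[i] <- iv[2] - sl; e0[i] <- iv[2] }
      chrom[i] <- m$chrom; strand[i] <- st; source_id[i] <- m$id
    }
  }

  keep <- rep(TRUE, n)
  if (!config$pap_enabled) keep <- classes == "mRNA"
  pre_size <- keep
  keep <- keep & ins_len >= config$size_window[1] &
    ins_len <= config$size_window[2]
  if (any(pre_size) && !any(keep)) {
    stop("size_window excludes every simulated molecule")
  }
  mol_idx <- which(keep)
  reps <- copies[mol_idx]
  ridx <- rep(mol_idx, reps)
  nr <- length(ridx)
  if (nr == 0L) return(empty())

  read_seq <- substr(paste0(seqs[ridx], strrep("A", tails[ridx])), 1L, RL)
  if (config$error_rate > 0) {
    lens <- nchar(read_seq)
    nmut <- stats::rbinom(nr, lens, config$error_rate)
    bases <- c("A", "C", "G", "T")
    for (j in which(nmut > 0L)) {
      pos <- sample.int(lens[j], nmut[j])
      ch <- strsplit(read_seq[j], "")[[1L]]
      for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
      read_seq[j] <- paste(ch, collapse = "")
    }
  }
  read_id <- sprintf("read%07d", seq_len(nr))
  truth <- data.frame(
    read_id = read_id,
    molecule_id = sprintf("mol%07d", ridx),
    class = classes[ridx],
    source_id = source_id[ridx],
    chrom = chrom[ridx], start = s0[ridx], end = e0[ridx],
    strand = strand[ridx],
    insert_length = ins_len[ridx], tail_length = as.integer(tails[ridx]),
    category = unname(.CLASS_CATEGORY[classes[ridx]]),
    stringsAsFactors = FALSE)
  structure(list(
    reads = data.frame(read_id = read_id, sequence = read_seq,
                       qualities = strrep("I", nchar(read_seq)),
                       stringsAsFactors = FALSE),
    truth = truth, config = config), class = "SimLibrary")
}

#' @export
print.SimLibrary <- function(x, ...) {
  cat(sprintf("SimLibrary: %d reads from %d molecules (seed %d)\n",
              nrow(x$reads), length(unique(x$truth$molecule_id)),
              x$config$seed))
  if (nrow(x$truth)) print(table(x$truth$class))
  invisible(x)
}

#' Emit the simulator's ground-truth alignments
#'
#' Converts the truth table to a `GRanges` of perfect alignments (one per
#' emitted read), optionally written as BED6, so the assignment, miRNA and
#' QC stages can be exercised without an external aligner.
#'
#' @param sim a `SimLibrary`.
#' @param path optional BED6 output path.
#' @return `GRanges` with `read_id` metadata.
#' @export
emit_truth_alignments <- function(sim, path = NULL) {
  tr <- sim$truth
  gr <- if (nrow(tr)) {
    genomic_intervals(tr$chrom, tr$start, tr$end, tr$strand,
                      read_id = tr$read_id)
  } else GenomicRanges::GRanges()
  if (!is.null(path)) {
    g <- gr
    names(g) <- if (length(g)) tr$read_id else NULL
    write_bed(g, path)
  }
  gr
}

#' Write a simulated library to disk
#'
#' @param sim a `SimLibrary`.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return named vector of the written paths, invisibly.
#' @export
write_sim_library <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fq <- file.path(dir, paste0(prefix, ".fastq.gz"))
  bed <- file.path(dir, paste0(prefix, ".truth.bed"))
  tsv <- file.path(dir, paste0(prefix, ".truth.tsv"))
  cfg <- file.path(dir, paste0(prefix, ".config.json"))
  write_fastq(sim$reads, fq)
  emit_truth_alignments(sim, bed)
  utils::write.table(sim$truth, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(unclass(sim$config), cfg, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(fastq = fq, truth_bed = bed, truth_tsv = tsv, config = cfg))
}
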