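make_gtf <- function(lines) {
  f <- tempfile(fileext = ".gtf")
  writeLines(lines, f)
  f
}

attrs <- function(g, t, b = "protein_coding") {
  sprintf('gene_id "%s"; transcript_id "%s"; gene_type "%s";', g, t, b)
}

test_that("GTF parsing converts 1-based inclusive to 0-based half-open", {
  f <- make_gtf(c(
    paste("chr1\tsrc\texon\t101\t200\t.\t+\t.", attrs("g1", "t1"), sep = "\t"),
    paste("chr1\tsrc\texon\t1\t200\t.\t+\t.", attrs("g2", "t2"), sep = "\t"),
    paste("chr1\tsrc\texon\t801\t1000\t.\t+\t.", attrs("g2", "t2"), sep = "\t")))
  tx <- parse_gtf(f)
  e1 <- tx$exons[["t1"]]
  expect_equal(GenomicRanges::start(e1) - 1L, 100L)  # 0-based start
  expect_equal(GenomicRanges::end(e1), 200L)         # exclusive end
  t2 <- tx$transcripts[tx$transcripts$transcript_id == "t2", ]
  expect_equal(t2$span_start, 0)
  expect_equal(t2$span_end, 1000)
  expect_equal(length(tx$exons[["t2"]]), 2L)
})

test_that("a GTF with only gene lines yields no transcripts, with a warning", {
  f <- make_gtf(paste("chr1\tsrc\tgene\t1\t100\t.\t+\t.",
                      attrs("g1", NA), sep = "\t"))
  expect_warning(tx <- parse_gtf(f), "no exon")
  expect_equal(nrow(tx$transcripts), 0)
})

test_that("interval merge handles overlap, book-ending and contract checks", {
  gr <- genomic_intervals("chr1", c(0, 5), c(10, 20), "+")
  m <- merge_intervals(gr)
  expect_equal(GenomicRanges::start(m) - 1L, 0L)
  expect_equal(GenomicRanges::end(m), 20L)
  # half-open adjacency merges
  m2 <- merge_intervals(genomic_intervals("chr1", c(0, 10), c(10, 20), "+"))
  expect_equal(length(m2), 1L)
  expect_error(merge_intervals(genomic_intervals("chr1", c(0, 5), c(10, 20),
                                                 c("+", "-"))),
               "strand")
  expect_error(genomic_intervals("chr1", 5, 5), "start < end")
})

test_that("subtraction removes covered bases, strand-aware", {
  a <- genomic_intervals("chr1", 0, 100, "+")
  b <- genomic_intervals("chr1", 40, 60, "+")
  d <- subtract_intervals(a, b)
  expect_equal(GenomicRanges::start(d) - 1L, c(0L, 60L))
  expect_equal(GenomicRanges::end(d), c(40L, 100L))
  expect_equal(length(subtract_intervals(a, a)), 0L)
  # opposite strand does not subtract
  bm <- genomic_intervals("chr1", 40, 60, "-")
  expect_equal(length(subtract_intervals(a, bm)), 1L)
  expect_error(subtract_intervals(
    genomic_intervals("chr1", c(0, 5), c(10, 20), "+"), b), "merged")
})

test_that("derived introns are span minus merged exons", {
  ex <- genomic_intervals("chr1", c(0, 800), c(200, 1000), "+")
  intr <- derive_introns(ex)
  expect_equal(GenomicRanges::start(intr) - 1L, 200L)
  expect_equal(GenomicRanges::end(intr), 800L)
  expect_equal(length(derive_introns(genomic_intervals("chr1", 0, 500, "+"))),
               0L)
})

test_that("non-mature derivation is strand-aware primary minus mature", {
  prim <- genomic_intervals("chr1", 0, 80, "+")
  mat <- genomic_intervals("chr1", 10, 32, "+")
  nm <- derive_nonmature(prim, mat)
  expect_equal(GenomicRanges::start(nm) - 1L, c(0L, 32L))
  expect_equal(GenomicRanges::end(nm), c(10L, 80L))
  # mature on the opposite strand leaves primary untouched
  nm2 <- derive_nonmature(prim, genomic_intervals("chr1", 10, 32, "-"))
  expect_equal(GenomicRanges::width(nm2), 80L)
})

test_that("miRBase-style GFF3 parses into named primary and mature sets", {
  ref <- toy()
  mir <- parse_mirna_gff3(ref$files$mirna_gff3)
  expect_equal(length(mir$primary), 4L)
  expect_equal(length(mir$mature), 8L)
  expect_true(all(grepl("^toy-mir", names(mir$primary))))
  expect_true(all(grepl("^MIMAT", GenomicRanges::mcols(mir$mature)$accession)))
  # every mature arm lies inside its primary hairpin
  ov <- GenomicRanges::countOverlaps(mir$mature, mir$primary,
                                     type = "within")
  expect_true(all(ov >= 1))
})

test_that("BED parsing keeps 0-based coordinates and strandless records", {
  f <- tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100\tx\t0\t+", f)
  f3 <- tempfile(fileext = ".bed")
  writeLines("chr1\t200\t300", f3)
  gr <- parse_bed(f)
  gr3 <- parse_bed(f3)
  expect_equal(GenomicRanges::start(gr) - 1L, 0L)
  expect_equal(GenomicRanges::start(gr3) - 1L, 200L)
  expect_equal(as.character(GenomicRanges::strand(gr)), "+")
  expect_equal(as.character(GenomicRanges::strand(gr3)), "*")
  # a strand of "." also means either strand
  fd <- tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20\ty\t0\t.", fd)
  expect_equal(as.character(GenomicRanges::strand(parse_bed(fd))), "*")
  # round trip through the BED writer preserves occupancy
  f2 <- tempfile(fileext = ".bed")
  write_bed(gr, f2)
  gr2 <- parse_bed(f2)
  expect_equal(occupancy(gr2, 400), occupancy(gr, 400))
})

test_that("derived sets match per-base brute force on random inputs", {
  set.seed(7)
  for (i in 1:50) {
    a <- merge_intervals(random_granges(20, N = 5000, strands = "+"))
    b <- merge_intervals(random_granges(20, N = 5000, strands = "+"))
    d <- subtract_intervals(a, b)
    oa <- occupancy(a, 5000)[["+"]]
    ob <- occupancy(b, 5000)[["+"]]
    expect_equal(occupancy(d, 5000)[["+"]], oa & !ob)
    m <- merge_intervals(GenomicRanges::sort(c(a, b)))
    expect_equal(occupancy(m, 5000)[["+"]], oa | ob)
  }
})

test_that("bundle serialization round-trips layer occupancy", {
  ref <- toy()
  dir <- tempfile("bundle")
  write_annotation_bundle(ref$bundle, dir)
  back <- read_annotation_bundle(dir)
  for (layer in c("exon_index", "intron_index", "trna_index", "repeat_index",
                  "mirna_nonmature")) {
    for (chrom in c("toyA", "toyB")) {
      expect_equal(occupancy(back[[layer]], 1e5, chrom),
                   occupancy(ref$bundle[[layer]], 1e5, chrom),
                   info = paste(layer, chrom))
    }
  }
  # biotype map survives
  expect_equal(back$gene_biotype[["GENE1"]], "protein_coding")
  expect_equal(back$gene_biotype[["SNORD1"]], "snoRNA")
})
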