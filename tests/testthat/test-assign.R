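# a compact hand-built bundle for targeted assignment cases: two same-strand
# genes with overlapping exons, an exon sitting on top of a repeat, and an
# isolated repeat
two_gene_bundle <- function() {
  gtf <- tempfile(fileext = ".gtf")
  at <- function(g, b) sprintf(
    'gene_id "%s"; transcript_id "%s.t"; gene_type "%s";', g, g, b)
  writeLines(c(
    sprintf("chr1\ts\texon\t101\t400\t.\t+\t.\t%s", at("A", "protein_coding")),
    sprintf("chr1\ts\texon\t301\t600\t.\t+\t.\t%s", at("B", "snoRNA")),
    sprintf("chr1\ts\texon\t1001\t1200\t.\t+\t.\t%s", at("C", "miRNA"))), gtf)
  rep_bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t150\t250\trep_under_exon\t0\t+",
               "chr1\t2000\t2100\trep_alone\t0\t+"), rep_bed)
  build_annotation_bundle(gtf, repeats = rep_bed)
}

test_that("layer priority and strandedness drive categorization", {
  b <- two_gene_bundle()
  aln <- genomic_intervals(
    "chr1",
    c(150, 2010, 1000, 120),
    c(180, 2060, 1040, 160),
    c("+", "+", "-", "-"),
    read_id = paste0("r", 1:4))
  cats <- categorize_reads(aln, b)
  expect_equal(cats[1], "exon")        # exon wins over the repeat beneath it
  expect_equal(cats[2], "repeat")      # repeat-only overlap
  expect_equal(cats[3], "unannotated") # antisense to exon C only
  expect_equal(cats[4], "unannotated") # antisense to exon A and its repeat
})

test_that("adding a repeat under an existing exon changes no category", {
  ref <- toy()
  set.seed(11)
  sim <- simulate_library(ref, sim_config(seed = 11, n_reads = 2000))
  aln <- emit_truth_alignments(sim)
  before <- categorize_reads(aln, ref$bundle)
  b2 <- ref$bundle
  # duplicate every exon interval into the repeat layer
  ex <- b2$exon_index
  GenomicRanges::mcols(ex) <- NULL
  b2$repeat_index <- c(b2$repeat_index, ex)
  after <- categorize_reads(aln, b2)
  expect_identical(before, after)
})

test_that("category counts conserve the aligned total", {
  ref <- toy()
  set.seed(5)
  for (n in c(0, 1, 500)) {
    aln <- if (n == 0) GenomicRanges::GRanges() else {
      g <- random_granges(n, N = 9e4, chrom = "toyA", max_w = 60)
      GenomicRanges::mcols(g)$read_id <- paste0("r", seq_len(n))
      g
    }
    cc <- count_categories(aln, ref$bundle)
    expect_equal(cc$exon + cc$intron + cc$trna + cc$`repeat` + cc$unannotated,
                 cc$aligned_total)
    expect_equal(cc$aligned_total, n)
  }
})

test_that("categorization matches the per-base brute-force oracle", {
  ref <- toy()
  layers <- list(exon = ref$bundle$exon_index,
                 intron = ref$bundle$intron_index,
                 trna = ref$bundle$trna_index,
                 "repeat" = ref$bundle$repeat_index)
  set.seed(13)
  aln <- random_granges(400, N = 9.5e4, chrom = "toyA", max_w = 80)
  got <- categorize_reads(aln, ref$bundle)
  want <- oracle_categorize(aln, layers, N = 1e5, chrom = "toyA")
  expect_equal(got, want)
})

test_that("gene counting follows multicov semantics with strandedness", {
  b <- two_gene_bundle()
  # one read inside gene A only
  one <- genomic_intervals("chr1", 110, 150, "+", read_id = "r1")
  expect_equal(count_genes(one, b)[["A"]], 1L)
  expect_equal(count_genes(one, b)[["B"]], 0L)
  # a read spanning the A/B exon overlap increments both genes
  both <- genomic_intervals("chr1", 320, 360, "+", read_id = "r2")
  cg <- count_genes(both, b)
  expect_equal(cg[["A"]], 1L)
  expect_equal(cg[["B"]], 1L)
  # antisense read counts nothing in forward mode, counts in reverse mode
  anti <- genomic_intervals("chr1", 110, 150, "-", read_id = "r3")
  expect_equal(count_genes(anti, b)[["A"]], 0L)
  expect_equal(count_genes(anti, b, strand_mode = "reverse")[["A"]], 1L)
  expect_equal(count_genes(anti, b, strand_mode = "both")[["A"]], 1L)
})

test_that("gene counts match a naive all-pairs overlap oracle", {
  ref <- toy()
  set.seed(17)
  aln <- random_granges(300, N = 6e4, chrom = "toyA", max_w = 80)
  GenomicRanges::mcols(aln)$read_id <- paste0("r", 1:300)
  got <- count_genes(aln, ref$bundle)
  ex <- ref$bundle$exon_index
  want <- integer(length(got))
  names(want) <- names(got)
  for (i in seq_along(aln)) {
    s <- as.character(GenomicRanges::strand(aln))[i]
    hit <- GenomicRanges::start(ex) <= GenomicRanges::end(aln)[i] &
      GenomicRanges::end(ex) >= GenomicRanges::start(aln)[i] &
      as.character(GenomicRanges::seqnames(ex)) ==
        as.character(GenomicRanges::seqnames(aln))[i] &
      (as.character(GenomicRanges::strand(ex)) == s |
         as.character(GenomicRanges::strand(ex)) == "*")
    for (g in unique(GenomicRanges::mcols(ex)$gene_id[hit])) {
      want[[g]] <- want[[g]] + 1L
    }
  }
  expect_equal(as.integer(got), unname(want))
})

test_that("biotype summary attributes exon reads with deterministic ties", {
  b <- two_gene_bundle()
  # 4 reads in A only, 3 in B only, 3 in C
  aln <- c(genomic_intervals("chr1", rep(110, 4), rep(150, 4), "+"),
           genomic_intervals("chr1", rep(450, 3), rep(500, 3), "+"),
           genomic_intervals("chr1", rep(1010, 3), rep(1050, 3), "+"))
  GenomicRanges::mcols(aln)$read_id <- paste0("r", 1:10)
  bs <- summarize_biotypes(aln, b)
  expect_equal(bs$exon_total, 10L)
  expect_equal(unname(bs$counts[c("protein_coding", "snoRNA", "miRNA")]),
               c(4L, 3L, 3L))
  expect_equal(sum(bs$counts), bs$exon_total)
  expect_equal(unname(bs$fractions["protein_coding"]), 0.4)

  # tie case: read covering the A/B overlap equally goes to the larger
  # overlap; here A gives 100-300 of exon, B 300-360 -> A wins on overlap
  tie <- genomic_intervals("chr1", 250, 350, "+", read_id = "t")
  bt <- summarize_biotypes(tie, b)
  expect_equal(names(bt$counts), "protein_coding")
  # exactly-equal overlap resolves lexicographically (A before B)
  eq <- genomic_intervals("chr1", 320, 340, "+", read_id = "e")
  be <- summarize_biotypes(eq, b)
  expect_equal(names(be$counts), "protein_coding")
})

test_that("summed-count filter applies strict inequality at the boundary", {
  m <- matrix(c(20, 1, 10, 10, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  expect_equal(rownames(filter_summed_counts(m, 20)), "A")
  expect_equal(rownames(filter_summed_counts(m, 0)), c("A", "B"))
  set.seed(3)
  r <- matrix(rpois(600, 5), nrow = 100)
  expect_equal(filter_summed_counts(r, 30),
               r[rowSums(r) > 30, , drop = FALSE])
})
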