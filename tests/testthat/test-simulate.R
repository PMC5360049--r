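test_that("same seed and config reproduce the library byte for byte", {
  ref <- toy()
  cfg <- sim_config(seed = 101, n_reads = 800)
  s1 <- simulate_library(ref, cfg)
  s2 <- simulate_library(ref, cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  d1 <- tempfile(); d2 <- tempfile()
  write_sim_library(s1, d1)
  write_sim_library(s2, d2)
  expect_identical(readLines(file.path(d1, "sim.truth.bed")),
                   readLines(file.path(d2, "sim.truth.bed")))
  # a different seed changes the reads
  s3 <- simulate_library(ref, sim_config(seed = 102, n_reads = 800))
  expect_false(identical(s1$reads$sequence, s3$reads$sequence))
})

test_that("toy reference is deterministic and internally consistent", {
  r1 <- build_toy_reference(5)
  r2 <- build_toy_reference(5)
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  expect_identical(readLines(r1$files$gtf), readLines(r2$files$gtf))
  b <- r1$bundle
  # mature arms inside their primaries, same strand
  ov <- GenomicRanges::countOverlaps(b$mirna_mature, b$mirna_primary,
                                     type = "within")
  expect_true(all(ov >= 1))
  # no degenerate intervals anywhere
  for (layer in c("exon_index", "intron_index", "trna_index",
                  "repeat_index", "mirna_nonmature")) {
    expect_true(all(GenomicRanges::width(b[[layer]]) > 0), info = layer)
  }
})

test_that("truth intervals stay inside their source molecules", {
  ref <- toy()
  sim <- simulate_library(ref, sim_config(seed = 55, n_reads = 3000))
  tr <- sim$truth
  gr <- emit_truth_alignments(sim)
  # every mature-miRNA read is contained in a mature arm
  mi <- gr[tr$class == "miRNA"]
  expect_true(all(GenomicRanges::countOverlaps(
    mi, ref$bundle$mirna_mature, type = "within") >= 1))
  # every intronic read inside the intron layer
  ii <- gr[tr$class == "intronic"]
  expect_true(all(GenomicRanges::countOverlaps(
    ii, ref$bundle$intron_index, type = "within") >= 1))
  # categories implied by the annotation match the truth labels
  expect_equal(categorize_reads(gr, ref$bundle), tr$category)
})

test_that("class mix is recovered within binomial error at the molecule level", {
  ref <- toy()
  cfg <- sim_config(seed = 202, n_reads = 20000, size_window = c(1, 10000))
  sim <- simulate_library(ref, cfg)
  first <- !duplicated(sim$truth$molecule_id)
  n <- sum(first)
  for (cl in names(cfg$class_mix)) {
    p <- cfg$class_mix[[cl]]
    obs <- mean(sim$truth$class[first] == cl)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(obs - p), 3 * se,
              label = sprintf("class %s: %.4f vs %.4f", cl, obs, p))
  }
})

test_that("chemistry controls: no PAP keeps only mRNA, no RT kills all", {
  ref <- toy()
  base <- sim_config(seed = 303, n_reads = 4000)
  full <- simulate_library(ref, base)
  no_pap <- simulate_library(ref, sim_config(seed = 303, n_reads = 4000,
                                             pap_enabled = FALSE))
  expect_true(all(no_pap$truth$class == "mRNA"))
  expect_equal(sum(no_pap$truth$class == "mRNA"),
               sum(full$truth$class == "mRNA"))
  no_rt <- simulate_library(ref, sim_config(seed = 303, n_reads = 4000,
                                            rt_enabled = FALSE))
  expect_equal(nrow(no_rt$reads), 0L)
})

test_that("RT drop-off gives geometric insert lengths for long RNAs", {
  ref <- toy()
  p <- 0.01
  cfg <- sim_config(seed = 404, n_reads = 10000, rt_dropoff_p = p,
                    class_mix = c(mRNA = 1), amp_bias_sigma = 0,
                    size_window = c(1, 100000))
  sim <- simulate_library(ref, cfg)
  lens <- sim$truth$insert_length
  mean_expected <- 1 / p
  se <- sqrt((1 - p) / p^2) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - mean_expected), 3 * se)
})

test_that("error-free miRNA libraries round-trip exactly through preprocessing", {
  ref <- toy()
  cfg <- sim_config(seed = 505, n_reads = 1000, error_rate = 0,
                    class_mix = c(miRNA = 1))
  sim <- simulate_library(ref, cfg)
  expect_true(all(sim$truth$insert_length == 22))
  fq <- tempfile(fileext = ".fastq")
  write_fastq(sim$reads, fq)
  out <- tempfile(fileext = ".fastq")
  st <- process_fastq(fq, out)
  expect_equal(st$reads_out, nrow(sim$reads))  # everything survives
  kept <- read_fastq(out)
  expect_true(all(nchar(kept$sequence) == 22))
  # clipped inserts equal the mature-arm genomic sequence
  arm_seq <- vapply(ref$sources$anchored$miRNA, function(m) m$seq, "")
  names(arm_seq) <- vapply(ref$sources$anchored$miRNA,
                           function(m) m$id, "")
  src <- sim$truth$source_id[match(kept$read_id, sim$truth$read_id)]
  expect_identical(kept$sequence, unname(arm_seq[src]))
})

test_that("amplification duplicates share molecule ids", {
  ref <- toy()
  cfg <- sim_config(seed = 606, n_reads = 5000, amp_bias_sigma = 1.0)
  sim <- simulate_library(ref, cfg)
  expect_gt(nrow(sim$truth), length(unique(sim$truth$molecule_id)))
  dup <- sim$truth[duplicated(sim$truth$molecule_id) |
                   duplicated(sim$truth$molecule_id, fromLast = TRUE), ]
  if (nrow(dup)) {
    by_mol <- split(dup$source_id, dup$molecule_id)
    expect_true(all(vapply(by_mol, function(x) length(unique(x)) == 1, TRUE)))
  }
})

test_that("contradictory size windows are rejected", {
  ref <- toy()
  cfg <- sim_config(seed = 1, n_reads = 100, class_mix = c(miRNA = 1),
                    size_window = c(30, 40))  # arms are 22nt
  expect_error(simulate_library(ref, cfg), "size_window")
  expect_error(sim_config(class_mix = c(miRNA = 0.5)), "sum to 1")
  expect_error(sim_config(rt_dropoff_p = 0), "rt_dropoff_p")
})
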