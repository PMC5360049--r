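# stakit

An R package for the informatics of **poly(A)-tailed RNA sequencing
libraries** — libraries built by single-tube chemistry in which poly(A)
polymerase appends a tail to every RNA 3' end (miRNA, snoRNA, tRNA, rRNA
and mRNA alike), an anchored oligo-dT primes reverse transcription at the
tail/insert junction, and the whole lysate is preamplified in one tube.
It is aimed at groups sequencing small-RNA + mRNA joint libraries from
low cell inputs who need the non-standard preprocessing and counting this
chemistry requires.

The package provides:

* **Tail preprocessing** — detection and clipping of the 3'-terminal A-run
  (reads kept when the run is ≥ 9 bases, i.e. more than eight As), with a
  minimum clipped-insert length of 18 bases so sub-alignable reads never
  reach the aligner.
* **Hierarchical strand-aware assignment** — each aligned read goes to the
  first layer in the order *exon > intron > tRNA > repeat* with same-strand
  overlap, else *unannotated*; gene-level counts use multicov semantics;
  exon reads are summarized by gene biotype.
* **Mature-miRNA quantification** — reads overlapping the hairpin
  *primary-minus-mature* remainder (loop/overhangs) are removed, survivors
  counted against mature arms.
* **Library QC** — gene-body coverage over 100 length-percentile bins
  (exposing the chemistry's 3' bias), RPM-normalized stranded bedGraph
  tracks (`value = depth × 10⁶ / aligned reads`), and a JSON composition
  report.
* **A chemistry-aware simulator** — a deterministic toy genome plus a
  generative read model (class mix → 3'-anchored geometric inserts →
  poly(A) tail → size selection → lognormal amplification → substitution
  errors) with per-read ground truth, including the no-PAP / no-RT control
  modes. All tests run against it; no downloads needed.

## Worked example

```r
library(stakit)

ref <- build_toy_reference(seed = 1)          # genome + GTF/GFF3/BED bundle
res <- run_pipeline(tempfile("run"),
                    sim = sim_config(seed = 3, n_reads = 5000),
                    reference = ref)
res
#> Composition report for library 'lib1'
#>   preprocess: 4851 -> 1992 reads (41.1% kept)
#>   categories: exon 92.5%, intron 2.7%, tRNA 0.0%, repeat 2.9%, unannotated 2.0%
#>   mature miRNA: 1992/1992 reads survived non-mature removal
print(res$gene_body)
#> Gene-body coverage over 13 transcripts
#>   5' half (bins 1-50):   0.000
#>   3' half (bins 51-100): 1.000
```

Reading the output: only ~41% of simulated reads survive preprocessing
because 50-base reads cannot reveal the tail of inserts longer than ~41
bases (tRNA at 72 nt, snoRNA at ~110–130 nt are lost exactly as in the real
protocol — hence tRNA at 0.0% after preprocessing, while it is ~16% of all
simulated molecules). The surviving library is exon-dominated (miRNA arms,
short 3' mRNA fragments), and because every surviving insert is ≤ 41 nt and
anchored at a polyadenylated 3' end, the gene-body profile collapses onto
the extreme 3' bins — the signature of oligo-dT-anchored chemistry.

Individual stages are exposed as plain functions
(`process_fastq()`, `build_annotation_bundle()`, `count_categories()`,
`count_genes()`, `summarize_biotypes()`, `quantify_mature_mirna()`,
`gene_body_coverage()`, `rpm_tracks()`, `filter_summed_counts()`,
`simulate_library()`), and a thin CLI wrapper with subcommands
(`simulate`, `preprocess`, `assign`, `mirna`, `qc`, `all`) is installed at
`inst/scripts/stakit`.

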