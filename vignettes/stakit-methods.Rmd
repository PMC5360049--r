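---
title: "Quantifying poly(A)-tailed small-RNA libraries with stakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying poly(A)-tailed small-RNA libraries with stakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stakit)
```

## The problem

Single-tube amplification chemistry builds joint mRNA + non-coding-RNA
libraries from very small cell inputs by polyadenylating every RNA 3' end
with poly(A) polymerase (PAP), priming reverse transcription with an
anchored oligo-dT (T20V) at the tail/insert junction, adding the 5' adapter
by template switching, and preamplifying everything in one tube. The
informatic consequences are distinctive:

* every usable read carries an encoded 3' poly(A) run that must be detected
  and clipped before alignment;
* reads derive from all RNA classes at once — miRNA, snoRNA, tRNA, rRNA,
  repeats, protein-coding fragments — so counting needs a strand-aware,
  prioritized assignment over layered annotation;
* long RNAs are captured from their polyadenylated 3' ends, so coverage is
  strongly 3'-biased, which QC must expose rather than hide;
* mature miRNA quantification must exclude reads touching the hairpin
  precursor outside the mature arms.

`stakit` implements this pipeline plus a chemistry-aware simulator that
produces ground-truth libraries, so every stage is testable without any
external download.

## Tail detection and clipping

A read is decomposed into a 5' insert and a 3' tail, the maximal terminal
run of `A`. Reads are kept when the run has at least `min_tail = 9` bases
(the "more than eight adenosines" selection rule) and the clipped insert has
at least `min_insert = 18` bases — the shortest alignment the downstream
aligner is configured to accept, so sub-alignable inserts are discarded
before alignment rather than after.

Two conservative choices are deliberate. `N` never counts as `A`; and by
default the run tolerates no interruptions (`max_interruptions = 0`), the
strictest reading of the selection rule. Because sequencing errors inside a
genuine tail do occur, `max_interruptions` can allow isolated (never
adjacent) non-`A` bases inside the run; the reported tail always begins with
an `A`, so interruption credits cannot extend the run past its true 5'
boundary. Qualities are clipped in lockstep with bases and no quality-based
trimming is performed. A side effect worth knowing: if a genomic insert
happens to end in `A`, those bases are indistinguishable from tail and are
clipped with it — 3'-terminal-A isoforms cannot be resolved by this
chemistry, and the clipper does not pretend otherwise.

A corollary used as a test invariant: clipped inserts never end in `A`, so
re-processing an already-processed stream keeps zero reads.

## Interval model and annotation layers

All internal coordinates are 0-based half-open; GTF/GFF3 are converted on
ingestion, BED is taken as-is, and BED/bedGraph output is bit-exact.
Standard parsing and interval arithmetic are delegated to
`rtracklayer`/`GenomicRanges`; the package's wrappers add the contracts the
pipeline relies on (single chromosome/strand for `merge_intervals`, merged
inputs for `subtract_intervals`) and the derivations:

* **introns** = transcript span minus merged exons, per transcript, unioned;
* **non-mature miRNA** = hairpin precursor (`miRNA_primary_transcript`)
  minus mature arms (`miRNA`), per-base and strand-aware.

Exons of all transcripts of a gene are merged per gene, because counting is
at gene level. The biotype attribute is accepted as `gene_type` or
`gene_biotype` (dialect drift). Strandless BED records — common in tRNA and
repeat tracks — match reads on either strand; a strict same-strand rule
would silently drop those layers entirely.

## Read assignment

Each primary alignment is assigned to the first layer, in the fixed order
**exon > intron > tRNA > repeat**, with at least `min_overlap = 1` base of
same-strand overlap; everything else is `unannotated`. Strandedness is
enforced: a read that is only antisense to a feature does not match it, so
antisense reads over genes surface as unannotated — a real and diagnostic
signal in this chemistry. The protocol is treated as forward-stranded (the
clipped insert is sense to the transcript, since the tail marks the RNA 3'
end); `strand_mode` exists because other conventions are conceivable for
other inputs.

Two counting semantics coexist on purpose:

* **category counts** count each read exactly once (so category percentages
  sum to 100%);
* **gene counts** follow multicov semantics — a read overlapping merged
  exons of two genes increments both.

Exon-read biotype summaries need a single gene per read; ties across
same-strand genes are resolved by largest exonic overlap, then lexicographic
gene id — deterministic and documented, since no convention is canonical.

The alignment footprint is the reference span (splice gaps included), which
matches how interval-overlap tools see a spliced BAM record. Only primary
alignments are counted, mirroring an aligner configured to report one
alignment per read.

## Mature miRNA quantification

The two-stage procedure: any read with ≥1 base of same-strand overlap with
the non-mature regions (loop, overhangs) is removed; survivors are counted
against the mature arms, multicov-style, keyed by accession where the
annotation provides one. Any-overlap counting is the default (the intersect
default); a containment flag is provided because the original convention is
not stated anywhere authoritative. When mature arms tile the whole
precursor, removal is a no-op and the procedure reduces to direct counting —
asserted as a test identity.

## QC outputs

**Gene-body coverage**: per-base depth over each transcript's exonic body,
oriented 5'→3' (bin 100 is the 3' end), rescaled to 100 percentile bins by
per-bin mean (so transcript length cancels), summed over transcripts and
normalized to 1. Transcripts shorter than 100 exonic bases are excluded —
one base per bin is the natural floor. Unlike generic QC tools that pool
both strands, depth here is strand-matched to the transcript: the protocol
is stranded, and pooling would let a gene's antisense partner contaminate
its profile (the toy reference contains exactly such a pair, and the
contamination is visible if strand matching is dropped). For this
chemistry the profile should lean heavily into the 3' half; the simulator
reproduces that and the tests require it.

**RPM tracks**: per-strand per-base depth × 10⁶ / aligned reads, emitted as
merged constant-value bedGraph intervals with fixed 6-decimal formatting and
deterministic chromosome order (byte-identical across runs). Values are
positive in both tracks; the negative rendering of the reverse strand is a
display convention. The conservation identity
`Σ value·length = 10⁶ · aligned bases / aligned reads` is tested.

**Composition report**: one JSON document per library combining
preprocessing survival, category distribution, biotype shares and
mature-miRNA bookkeeping; every percentage is recomputable from raw counts
included next to it.

## The simulator

`build_toy_reference()` writes a deterministic ~105 kb two-chromosome
genome with fixed feature coordinates and a seeded random base sequence:
multi-exon protein-coding genes on both strands (including two short
histone-like mRNAs of 500 and 800 exonic bases, so gene-body profiles keep
resolution at the RT-processivity scale), an antisense gene pair, a
repeat beneath an exon (priority test case), four miRNA hairpins with
primary + mature GFF3 records, snoRNA/tRNA/rRNA loci (one tRNA record
strandless), intergenic repeats, and a clean intergenic region. The base
immediately before each annotated molecule 3' end is forced non-`A` so that
clipping an appended tail recovers the insert exactly — without this, tail
clipping would (correctly) eat genomic terminal `A`s and exact round-trip
assertions would be ill-posed.

`simulate_library()` follows the chemistry: class → source molecule → insert
→ tail → size selection → amplification → errors → truncation to read
length. Defaults were chosen once as a realistic mixed library and are not
tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `class_mix` | miRNA .30, snoRNA .10, tRNA .15, rRNA .15, repeat .05, mRNA .15, intronic .05, intergenic .05 | a small-RNA-dominated mixed library with visible rRNA/tRNA background and mRNA-fragment carryover |
| `tail_length_dist` | constant 20 | the anchored T20V primer fixes the encoded tail length; the true post-PAP distribution is unknown (smears), so the distribution is pluggable |
| `rt_dropoff_p` | 0.01 | geometric insert mean 100 nt for long RNAs, a typical RT processivity scale |
| `amp_bias_sigma` | 0.25 | mild lognormal amplification spread; duplicates share a molecule id |
| `error_rate` | 0.001 | Illumina-scale substitution rate |
| `size_window` | (18, 1000) | lower bound = alignability; upper effectively open for whole-transcriptome runs (miRNA-sized gel cuts would use ~(18, 30)) |
| `read_length` | 50 | short-read sequencing of these libraries |

Mechanics worth noting:

* Long-RNA inserts are anchored at the transcript 3' end and extended
  5'-ward with per-base termination probability `rt_dropoff_p` — this single
  mechanism generates the 3' coverage bias. Intron/repeat/intergenic
  fragments draw a uniform 3' end inside their parent interval first
  (fragmented or nascent molecules have arbitrary 3' ends).
* Truth intervals record the footprint a perfect aligner would report for
  the clipped insert: the 5'-most `min(insert, read_length)` insert bases
  (reference span for spliced inserts). With 50-base reads, inserts longer
  than 41 nt leave fewer than nine visible tail bases, so such reads fail
  tail selection — faithful to the real protocol, where long inserts
  require longer reads or are lost at preprocessing.
* `pap_enabled = FALSE` models the no-PAP control: all per-molecule
  attributes are drawn before the filter, so the mRNA-class yield is
  identical to the matched full run at the same seed and every
  non-preadenylated class yields exactly zero reads. `rt_enabled = FALSE`
  yields an empty library.
* Amplification copies are `max(1, round(w))` with lognormal `w`: σ = 0
  means exactly one copy, and no molecule vanishes at the PCR step.
  Because duplication makes read-level class fractions overdispersed, the
  class-mix recovery invariant is asserted at the unique-molecule level,
  where the multinomial null is exact.

What the simulator does **not** emulate: indels and structural errors,
ligation-style adapter biases, template-switch strand invasion, isomiR end
heterogeneity, polymerase-fidelity effects, and real genomic repeat
structure (repeats are annotation intervals, not homologous sequence — so
multimapping, a genuine difficulty of real repeat-derived reads, is absent).
Passing tests therefore validate the pipeline's logic and bookkeeping, not
its behavior under alignment ambiguity.

## Numerical and degenerate-input choices

* Half-open adjacency merges (`[0,10) + [10,20) = [0,20)`).
* Empty inputs return zeroed statistics rather than errors; an empty
  coverage profile warns and returns all-zero bins.
* `rpm_tracks` refuses `aligned_total = 0` (the normalization is undefined).
* A size window that excludes every simulated molecule is a configuration
  error, not an empty library.
* bedGraph values are written with fixed 6 decimals; chromosome order is
  lexicographic and stable.

## Problem sizes used in the test suite

The randomized oracle comparisons run at 1,000 instances over 10⁵-base
genomes (interval algebra, hairpin layouts), 10,000 random reads (tail
filtering) and 50,000-read simulated libraries (assignment, 3'-bias), with
fixed seeds throughout; these sizes give the property checks comfortable
statistical teeth while keeping the default suite quick on one CPU.

## Limitations

Alignment itself is out of scope: the pipeline consumes coordinate-sorted
BAM/BED produced elsewhere, and the simulator's truth BED stands in for an
aligner in all bundled tests. Multimapper handling beyond "count primary
records" (rescue, EM reassignment), UMI logic (the chemistry has none) and
isomiR resolution are out of scope; 3'-terminal-A isoforms are
fundamentally unresolvable under this chemistry, as discussed above.
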