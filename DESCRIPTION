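Package: stakit
Title: Informatics Pipeline for Poly(A)-Tailed Small-RNA Sequencing Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying small and large RNAs from sequencing
    libraries prepared by single-tube polyadenylation chemistry, in which
    every RNA 3' end carries an enzymatically added poly(A) tail. Provides
    poly(A)-tail detection and clipping with insert-length filtering,
    strand-aware hierarchical assignment of aligned reads to exon, intron,
    tRNA and repeat layers, mature-microRNA quantification by subtracting
    hairpin precursor regions, gene-body coverage and RPM-normalized
    bedGraph quality-control outputs, and a chemistry-aware read simulator
    that generates ground-truth libraries so the whole pipeline can be
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    GenomicAlignments,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
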