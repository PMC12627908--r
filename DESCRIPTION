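Package: uceforge
Title: Ultraconserved-Element Probe Design, In Silico Capture and Locus-Matrix
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for designing target-capture probe (bait)
    sets for ultraconserved elements (UCEs) from soft-masked genome assemblies,
    testing them by in silico capture, and computing downstream locus-matrix
    statistics. Implements error-free paired-end read simulation, a
    divergence-tolerant k-mer seed-and-extend read mapper, BED-style interval
    merging and mask/length filtering, shared-locus presence tables with
    exemplar-count selection, 120-bp probe tiling with GC/mask screening and
    duplicate-locus removal, align-back multi-hit filtering with buffered locus
    slicing, probe-to-assembly capture with flank extraction and one-to-one
    duplicate screening, completeness-filtered supermatrix assembly,
    parsimony-informative site counts, uncorrected p and Kimura 1980 distances
    with pairwise deletion, binary SNP extraction, and principal component
    analysis. A synthetic-clade generator plants conserved cores along a
    phylogeny so the whole pipeline is testable end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    jsonlite,
    stringi,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
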