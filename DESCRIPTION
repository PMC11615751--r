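Package: acetylink
Title: Integrative H3K27ac ChIP-Seq and RNA-Seq Peak-Gene Linking
Version: 0.1.0
Authors@R: person("Maintainer", "Acetylink", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrative epigenome-transcriptome analysis pipeline for
    two-condition H3K27ac ChIP-Seq and RNA-Seq experiments. Normalizes
    per-peak acetylation signal (read-depth and peak-length scaled, with
    input subtraction and background rescaling), computes FPKM expression,
    performs a self-contained negative-binomial two-group differential test
    on peak and gene counts, links peaks to genes whose transcription start
    sites fall within a configurable window, correlates peak signal with
    gene expression across samples, classifies linked pairs into four
    fold-change quadrants (PP/NN/PN/NP), ranks top peak-genes, and tests
    gene lists for over-representation. A coupled count simulator with
    planted peak-gene classes provides ground truth for end-to-end
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    BiocGenerics,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    GenomicRanges,
    DESeq2,
    optparse
Config/testthat/edition: 3
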