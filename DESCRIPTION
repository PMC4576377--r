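Package: hicpanels
Title: Multi-Panel Visualization of Hi-C Interaction Matrices with
    Linear Genomic Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reads dense and sparse Hi-C interaction matrices, applies
    precomputed Knight-Ruiz balancing factors, and composes publication
    figures that juxtapose contact-matrix panels (square heatmap or
    45-degree rotated half matrix) with aligned linear genomic tracks:
    bedGraph histograms, BED-like tiles, chromatin-loop arcs, and domain
    triangles, across multiple experimental conditions on a common
    x-axis.  Includes a permutation test for enrichment of a continuous
    signal (for example replication timing) over interaction anchors
    against length-matched random loci, a deterministic synthetic-data
    generator for TAD-structured contact matrices and companion tracks,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), rtracklayer, GenomicRanges
Config/testthat/edition: 3
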