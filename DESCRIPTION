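Package: TADfusion
Title: Regulatory-Landscape Reconstruction of Chromosomal Translocations from 4C-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct and analyse the regulatory landscape of a
    chromosomal translocation from 4C-seq data. Provides in-silico restriction
    digestion and fragment-end coordinate systems, per-viewpoint 4C profile
    construction (fragment-end read counts, running-mean smoothing, RPM
    normalisation, Z-scores), derivative-chromosome coordinate maps with
    allele-dosage rescaling, interaction-peak calling against a two-sided
    monotonic (pool-adjacent-violators) background with a Tukey-fence residual
    threshold, restraint-based 3D chromatin modelling with ensemble selection,
    mirror-aware clustering and virtual Hi-C computation, and iterative
    directionality-index TAD-boundary calling with cross-iteration consensus.
    A seeded synthetic-data generator produces genomes, TAD landscapes, planted
    loops, translocations and overdispersed 4C counts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
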