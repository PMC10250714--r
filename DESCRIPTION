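Package: trescan
Title: Thyroid Hormone Response Element Scanning, Promoter Enrichment, and
    Ligand-Binding Curve Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scans genomes for degenerate nuclear-receptor response elements
    (TRE halfsites and DR0-6/DR4 direct repeats) on both strands with a joint
    mismatch budget, associates hits with gene models through strand-aware
    promoter windows around predicted transcription start sites, and tests
    whether genes with many nearby response elements are more strongly
    regulated in a differential-expression table (fold-ratio of absolute
    log2 fold changes, DEG/non-DEG count enrichment, two-tailed Welch t
    tests). Also fits the one-site total (saturation) binding model and the
    one-site competitive displacement model with the Cheng-Prusoff Ki
    correction to fluorescence-polarization dilution-series data. A
    synthetic-data generator (random genomes with planted motifs, expression
    tables with a motif-linked effect, noisy binding curves) makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
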