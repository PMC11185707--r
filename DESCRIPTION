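Package: cobindTargets
Title: Integrating Transcription-Factor Co-Binding with Mutant Expression to
    Call Direct Target Genes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates ChIP-seq peak sets for a pair of cooperating
    transcription factors (a Smad and its Schnurri partner being the
    motivating case) with RNA-seq differential expression from the
    corresponding mutants. Provides peak centroid geometry with a
    randomized positional null, overlap partitioning of two peak sets,
    conditional stratified false-discovery re-testing of paired
    differential-expression comparisons (Luperchio overlap analysis),
    distance-decay regulatory-potential scoring with rank-product direct
    target calling and a Kolmogorov-Smirnov activator/repressor verdict,
    partitioning of direct targets into co-regulated and
    factor-exclusive classes, high-occupancy-target (HOT) site
    co-occupancy screening against a multi-factor peak compendium, and
    Glass' effect-size screening of phenotype measurements. A synthetic
    data generator with known ground truth exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
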