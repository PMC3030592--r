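Package: lowdiv
Title: Cluster Resolvability Simulation and Deferred Cluster-Calling Rescue
    for Low-Diversity Sequencing Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for diagnosing and rescuing data loss in low-diversity
    Illumina Genome Analyzer libraries. Includes a Monte-Carlo simulation of
    cluster placement and resolvability on a flow-cell tile (with a
    closed-form Poisson companion model), deferred cluster-calling support
    (sequencing-cycle remapping of image-stack manifests and barcode
    rotation of FASTQ reads), in-line barcode demultiplexing with yield
    arithmetic and ANOVA significance testing, per-base and per-sequence
    Phred quality summaries, and genome-window read counting with
    percentile outlier filtering and paired-track comparison. A
    deterministic synthetic-fixture generator produces every input format
    the toolkit consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    rtracklayer,
    GenomicRanges,
    IRanges,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    S4Vectors,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
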