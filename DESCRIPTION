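Package: operomap
Title: Condition-Dependent Operon Maps from Prokaryotic RNA-Seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds condition-dependent operon maps for bacterial genomes from
    a single per-base RNA-seq coverage profile. A sliding-window correlation
    detector locates transcription start and end points, RPKM expression of
    coding and intergenic regions confirms a seed set of reference-annotated
    operons, and adjacent gene pairs are labelled as operon pairs, non-operon
    pairs, putative operon pairs or expressed gene pairs. Four genomic and
    transcriptomic features (intergenic distance, relative synonymous codon
    usage similarity, expression difference and intergenic expression) feed a
    random forest, a neural network and a support vector machine whose class
    calls are combined by simple majority voting; voted pairs are chained into
    a final operon map and checked against predicted promoter and terminator
    intervals. A synthetic transcriptome generator with full ground truth makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    randomForest,
    nnet,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
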