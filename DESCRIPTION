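Package: signovo
Title: Mutational Signature Refitting and De Novo Extraction from
    Residual Catalogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of somatic mutational signatures in cancer genomes
    for small cohorts. Generates SBS-96 mutation catalogs from VCF variant
    calls and an indexed reference genome, fits a panel of reference
    signatures to the catalog by per-sample non-negative least squares with
    forward or backward stepwise signature selection and a cost curve for
    model choice, extracts de novo signatures from the residual counts left
    unexplained by the fit using partially-fixed non-negative matrix
    factorization with leave-k-out cross-validation to choose the number of
    new signatures, and scores signature similarity with the Hellinger
    distance. Includes a multinomial catalog simulator for benchmarking and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    ggplot2,
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
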