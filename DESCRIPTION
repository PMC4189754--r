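Package: pdmodules
Title: Phenotype-Defining Functional Modules from Protein-Family
    Co-Occurrence
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers functional modules of protein families (Pfam and
    CAZy) from genome and metagenome-bin annotation profiles with a
    latent Dirichlet allocation topic model fitted by collapsed Gibbs
    sampling, ranks modules by their association with a binary phenotype
    such as lignocellulose degradation using completeness-score weights
    and F-measure-optimal thresholds, stabilizes modules across repeated
    runs into consensus modules via Hungarian matching and maximal-clique
    detection, evaluates phenotype classifiers by leave-one-out and
    repeated cross-validation with Clopper-Pearson intervals, predicts
    module occurrences in unlabeled samples, and detects gene clusters of
    module-annotated genes on replicons. Includes a synthetic-data
    generator with planted ground truth and a command-line pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Config/testthat/edition: 3
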