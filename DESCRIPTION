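Package: tissueMutAssoc
Title: Associating Cancer-Type-Specific Mutation Frequencies with Normal-Tissue Features
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for explaining cancer-type-specific somatic mutation
    frequencies of genes with transcriptomic and epigenomic features of the
    corresponding normal tissues. Implements gene-level mutation-frequency
    profiles from MAF-style catalogs, four candidate normal-tissue features
    (chromatin accessibility from 25-state model labels, own expression,
    pathway-neighbor activity and protein-interaction-partner activity, the
    latter two as permutation-based activity scores) plus a remote-neighbor
    control feature, a gap-split permutation test of association between
    mutational profiles and feature values across tissues with a permutation
    false discovery rate, within-tissue two-group comparisons with a one-sided
    Kolmogorov-Smirnov permutation test, and univariate and bivariate gene-set
    enrichment random walks with hypergeometric expected and conditional
    curves. A synthetic-data generator with planted ground truth supports
    calibration and power studies of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
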