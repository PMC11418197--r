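Package: v2gmap
Title: Variant-to-Gene Mapping via Chromatin Loops and Open Chromatin
Version: 0.1.0
Authors@R:
    person("V2G", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A variant-to-gene (V2G) analysis toolkit for regulatory
    genomics: builds 95% credible sets from GWAS summary statistics via
    approximate Bayes factors, constrains them to ATAC-seq open chromatin,
    consensus-merges multi-resolution Hi-C loops, annotates
    promoter-interacting open chromatin, nominates effector genes with
    descriptive statistics, benchmarks predictions against curated truth
    sets (precision/recall, concordance, permutation and proportion
    enrichment tests), clusters expression trajectories, and ships a
    planted-ground-truth synthetic data generator so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
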