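Package: triomics
Title: Integrative Analysis of Copy Number, DNA Methylation and Expression
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates per-sample DNA copy number, DNA methylation and mRNA
    expression profiles for a cancer cell-line panel. Converts segmented copy
    number, methylation beta values and variance-stabilized expression into
    per-gene binary aberration calls (gain, loss, hyper- and
    hypo-methylation, over- and under-expression) against designated normal
    controls, enumerates two- and three-way cross-platform aberration
    combinations, selects recurrently altered genes including an
    either-mechanism union rule, quantifies per-sample dependencies between
    aberration types with odds ratios and corrected chi-square tests
    (optionally conditioning on copy-number state), tests copy-number
    frequency against gene density with a Monte Carlo value-permutation
    test (genome-wide and per chromosome arm), identifies differentially
    methylated and expressed genes via M-values and t-tests, and clusters
    samples hierarchically. Ships a seeded synthetic three-platform data
    generator with planted ground truth so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    limma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
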