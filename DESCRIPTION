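Package: methdyn
Title: Intraindividual DNA Methylation Stability and Short-Term Gene
    Expression Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline asking whether day-to-day variation in DNA
    methylation explains short-term gene-expression dynamics within one
    individual. Provides reference-based cell-type deconvolution of
    methylation beta values by non-negative least squares, detection of
    dynamically expressed genes as coefficient-of-variation outliers
    (iterative Smirnov-Grubbs test within bins of mean log expression),
    cell-type composition/expression association (CEA) testing by nested
    linear-model ANOVA, and methylation/expression association (MEA)
    analysis on reference-day-relative values with linear models, partial
    R-squared under composition adjustment, and Spearman permutation
    tests. A synthetic-data generator produces longitudinal mixed-cell
    expression and methylation matrices with planted effects so every
    inference stage is verifiable offline.
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
    SummarizedExperiment,
    MASS,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'cea.R'
    'config.R'
    'deconvolution.R'
    'dynamic.R'
    'io.R'
    'mea.R'
    'methdyn-package.R'
    'pipeline.R'
    'simulate.R'
    'utils.R'
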