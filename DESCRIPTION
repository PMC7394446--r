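Package: mprabayes
Title: Bayesian Negative-Binomial Analysis of Massively Parallel Reporter Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully Bayesian framework for calling functional variants from
    massively parallel reporter assay (MPRA) barcode counts. Barcode-level DNA
    and RNA counts are modelled with negative binomial distributions whose
    means scale with per-sample sequencing depth and per-barcode plasmid input;
    gamma priors on all parameters are estimated empirically from the
    population of per-variant maximum likelihood estimates, either marginally,
    within annotation groups, or conditionally via adaptive t-kernel weights on
    continuous annotations. Per-variant joint posteriors yield a
    transcription-shift posterior whose highest density interval drives
    functional calls, with an optional region of practical equivalence. The
    package also provides an assay simulator with known ground truth, the
    classical activity t-test baseline, and ROC/PR evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    parallel,
    Rcpp,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'mprabayes-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'baselines.R'
    'cli.R'
    'fitAssay.R'
    'io.R'
    'mle.R'
    'nb.R'
    'posterior.R'
    'priors.R'
    'simulate.R'
    'utils.R'
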