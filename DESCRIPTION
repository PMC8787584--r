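Package: liabilityMR
Title: Two-Sample Mendelian Randomization for Binary Exposures with
    HEIDI Outlier Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization of a binary
    exposure on a binary outcome from GWAS summary statistics: reading,
    validation and allele harmonization of summary tables; instrument
    strength diagnostics (per-variant and combined R-squared, combined F
    statistic); six causal-effect estimators (multiplicative
    random-effects IVW, MR-Egger, weighted median, simple and weighted
    mode, and a GSMR-style precision-weighted estimator with
    HEIDI-outlier filtering); doubling-of-odds rescaling of
    binary-exposure estimates; Z-difference comparison against published
    observational odds or hazard ratios; and a calibrated simulator of
    two-sample GWAS summary statistics with known causal effect,
    pleiotropy regime and planted heterogeneous outliers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'liabilityMR-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'summary_io.R'
    'harmonize.R'
    'strength.R'
    'estimators.R'
    'gsmr.R'
    'scaling.R'
    'simulate.R'
    'pipeline.R'
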