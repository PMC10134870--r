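Package: coldflux
Title: Metabolic Robustness Analysis for Two-Temperature Growth Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for assessing metabolic robustness of a
    bacterium grown at two temperatures. Covers growth and substrate-uptake
    kinetics from OD600 and concentration time series, two-condition NMR
    metabolome robustness statistics (trend correlations, all-against-all
    correlation matrices, per-metabolite mean tests, fold-change contrasts),
    differential-expression summarization (TPM, DEG thresholds, COG
    enrichment, pathway DEG fractions), and constraint-based metabolic
    modeling: flux balance analysis on models in the community JSON schema,
    MILP integration of relative transcriptomic and metabolomic fold
    changes via consistency-score maximization, flux-split based metabolite
    change prediction, and pathway-level differential flux analysis with
    Kolmogorov-Smirnov tests. Includes a synthetic-data generator producing
    a toy central-carbon model and multi-omics tables with known ground
    truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
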