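Package: mavecal
Title: Calibration of Multiplexed Assays of Variant Effect into ACMG/AMP Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calibrates continuous functional-assay scores (for example from
    multiplexed assays of variant effect) for a single gene or domain into
    variant-level ACMG/AMP evidence strengths. Scores from pathogenic,
    benign, population-reference and synonymous variant samples are jointly
    modeled as a constrained multi-sample two-component skew-normal mixture
    fitted by expectation-maximization under a monotone density-ratio
    constraint. The fitted mixture yields a gene-specific prior probability
    of pathogenicity, local positive likelihood ratios, and point-based
    evidence-strength score thresholds, with uncertainty quantified by a
    stratified bootstrap. Includes a synthetic-data generator emulating the
    assumed sampling model, fit diagnostics, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
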