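Package: predfr
Title: Predator Functional Response and Molecular Gut-Content Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying arthropod predation on insect pests from
    laboratory predation trials and field molecular gut-content screening.
    Classifies functional-response type from the cubic proportion-consumed
    polynomial, fits Holling Type II/III disc equations by bounded nonlinear
    least squares to estimate instantaneous attack rate and handling time,
    and derives daily maximum predation rate, theoretical predation capacity
    and density-dependent search efficiency. Computes per-taxon and pooled
    positive DNA detection rates and predator community composition
    summaries, with exact binomial confidence intervals. Includes a seeded
    synthetic predation-trial and detection-table generator for parameter
    recovery experiments, CSV readers/writers for trial and detection
    tables, and a full-pipeline report builder.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
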