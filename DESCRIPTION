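Package: opdemand
Title: Behavioral-Economic Demand Analysis for Operant Drug
    Self-Administration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for operant drug self-administration
    experiments with long-access sessions and daily fixed-ratio (FR)
    escalation.  Classifies acquisition of self-administration from daily
    session records using a two-part criterion (2:1 active:inactive lever
    discrimination plus intake above the saline-control 95% confidence
    bound), fits the exponential behavioral-economic demand equation of
    Hursh and Silberberg to consumption-versus-unit-price data by
    nonlinear least squares on the log10 scale (individually or with a
    jointly estimated range constant k), derives the demand indices
    alpha, Q0, Pmax and Omax from the fitted curves, and compares groups
    with Welch t-tests and Fisher exact tests.  Includes a synthetic
    cohort generator that emulates a two-strain (SHR vs Wistar)
    adolescent nicotine self-administration design so the whole pipeline
    is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
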