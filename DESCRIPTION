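Package: dyadwcs
Title: Simulation and Analysis of Dyadic Perceptual Decision Making
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulating and analysing two-interval forced-choice
    contrast-discrimination experiments performed by dyads. Provides a
    generator for counterbalanced trial designs, a signal-detection
    simulator of private and joint decisions under configurable
    negotiation rules, cumulative-Gaussian (probit) psychometric fitting
    with conversion to maximum-slope sensitivity, per-dyad measures of
    collective performance (similarity, collective benefit, and an
    optimality index relative to the Weighted Confidence Sharing
    benchmark), the standard group-level statistics used with such
    designs (t-tests with Cohen's d, mixed-design ANOVA), and a
    reproducible end-to-end study pipeline with parameter-recovery
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
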