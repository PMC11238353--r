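Package: secondopinion
Title: Simulation and Evaluation of AI-Triggered Second-Opinion Diagnostic Protocols
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study arbitration protocols for binary diagnostic
    decisions in which a hidden AI classifier triggers a second human
    opinion whenever it disagrees with the first clinician. Provides a
    synthetic cohort and rater-panel generator parameterised by
    sensitivity/specificity, Monte-Carlo engines for the second-opinion
    and three-reader majority-vote protocols, macro-F1 scoring, the
    accompanying inferential toolkit (t-based confidence intervals,
    pairwise paired t-tests with Bonferroni correction, Pearson
    correlation), analytic and exhaustive-enumeration oracles for
    validating the simulation engine, and downstream analyses such as
    AI-accuracy sensitivity sweeps, agreement stratification and
    decision-switch accounting. Motivated by pulp-exposure prediction
    after advanced caries treatment, but applicable to any binary
    multi-reader setting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
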