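Package: scmeval
Title: Synthetic-Control Evaluation of Staggered Primary-Care Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for causal evaluation of organisational interventions in
    primary care (such as vertical integration of GP practices with an acute
    hospital) from monthly practice-level panels of unplanned-care rates.
    Fits a multivariate synthetic control per treated practice by nested
    optimisation of donor and predictor weights, derives per-practice
    difference-in-differences effects with placebo-based standard errors,
    pools effects across practices by inverse-variance meta-analysis with
    Cochran's Q, Higgins-Thompson I-squared and DerSimonian-Laird tau-squared,
    and converts pooled effects into avoided events and cost savings using
    reference-cost arithmetic. Includes a calibrated synthetic panel
    generator with latent-factor structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    quadprog,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
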