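Package: rootsplit
Title: Heterogeneous Treatment Effect Discovery in Randomised Trials via
    Honest Causal Forests and Root-Split Subgroups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploratory subgroup discovery in two-arm randomised
    controlled trials with a binary outcome. Implements classical univariable
    treatment-interaction screening with Bonferroni control, a strong-hierarchy
    penalised logistic regression over all treatment-by-covariate interactions,
    and an honest causal forest estimating conditional average treatment
    effects with an omnibus heterogeneity test, depth-weighted variable
    importance and doubly-robust subgroup effect estimates. The forest's root
    splits are tallied across trees to derive a data-driven threshold on the
    modal effect modifier, converting the forest into a clinically actionable
    two-subgroup partition with augmented inverse-propensity-weighted group
    average treatment effects. A calibrated synthetic trial generator and a
    simulation harness support validation of threshold recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    ranger,
    sandwich,
    lmtest,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
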