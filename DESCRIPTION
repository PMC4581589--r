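Package: dynmsm
Title: Dynamic Marginal Structural Models for Antiretroviral Switching Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Clone-censor-weight estimation of counterfactual survival under
    dynamic antiretroviral-therapy switching strategies defined by CD4-count
    thresholds, WHO clinical events and CD4-monitoring frequencies. Cohorts in
    person-period (4-weekly interval) form are expanded into per-strategy
    clones, artificially censored when follow-up becomes incompatible with a
    strategy, and reweighted by nonstabilized inverse-probability weights with
    a uniform-over-grace-period numerator; survival is estimated by weighted
    pooled logistic regression with nonparametric bootstrap confidence bands.
    Includes a synthetic cohort generator with a known data-generating
    mechanism and forced-regime simulation of ground-truth counterfactual
    survival for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
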