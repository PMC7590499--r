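Package: vacheck
Title: Validation of Computer-Coded Verbal Autopsy Against Gold-Standard
    Causes of Death
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate probabilistic verbal-autopsy (VA) coders
    against a gold-standard cause-of-death assignment such as the complete
    diagnostic autopsy. Implements an InterVA-style Bayesian cause-of-death
    engine driven by a user-supplied probbase (prior and
    indicator-given-cause conditional probabilities, with malaria/HIV
    prevalence adjustment and up-to-three-cause reporting), individual-level
    agreement metrics (per-cause confusion counts, sensitivity, specificity,
    predictive values, Cohen's kappa, chance-corrected concordance),
    population-level metrics (cause-specific mortality fractions with
    partial-likelihood weighting, CSMF accuracy and its chance-corrected
    version against a random-allocation baseline), and a validation harness
    that stresses the metrics across uninformative Dirichlet cause
    compositions. A synthetic-cohort generator reproduces the statistical
    structure of a hospital-based autopsy validation series so the full
    pipeline can be exercised without access to individual death records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
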