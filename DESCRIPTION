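Package: cogposet
Title: Poset-Based Classification of Cognitive Functioning Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds partially ordered set (poset) models of latent cognitive
    states from an attribute-measure incidence specification (a Q-matrix-style
    table mapping neuropsychological measures to the cognitive functions, and
    function levels, required to perform well on them), classifies subjects to
    states by Bayesian updating with two-component (mastery / non-mastery)
    response distributions per measure, aggregates state posteriors into
    per-function functioning probabilities via order-theoretic up-sets with
    confounded-state weighting, and runs downstream conversion-outcome
    analyses: cutoff subgroups, 2x2 contingency tables with Wald confidence
    intervals and Fisher exact tests, logistic prediction models with ROC/AUC,
    and conversion-aligned trajectory histograms. A synthetic cohort generator
    with known ground truth (latent states, state-dependent responses, APOE e4
    status, state-dependent conversion outcomes, longitudinal decline) makes
    the full pipeline testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
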