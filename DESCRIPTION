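Package: bilymph
Title: Bilateral Hidden Markov Model of Lymphatic Tumor Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models ipsilateral and contralateral lymph node involvement in
    oropharyngeal squamous cell carcinoma as a hidden Markov model over binary
    lymph node levels. Implements the directed-graph parameterization of the
    transition matrix with no self-healing, binomial diagnosis-time priors,
    midline-extension dynamics with a per-step crossing probability, the joint
    bilateral state distribution and cohort likelihood, affine-invariant
    ensemble MCMC inference with differential-evolution moves, Bayesian
    prediction of occult nodal disease risk given an imperfect clinical
    diagnosis, predicted and observed prevalence comparison, and a generative
    simulator of synthetic patient cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
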