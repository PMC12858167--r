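Package: driftdid
Title: Hierarchical Drift-Diffusion Modelling and Difference-in-Differences
    Causal Analysis for Perturbation Studies of Decision-Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing matched perceptual and value-based choice
    experiments in which a within-subject perturbation (for example inhibitory
    brain stimulation) is applied mid-experiment. Provides a synthetic-data
    generator reproducing the balanced 2(task) x 4(evidence) x 2(response)
    design with pre/post perturbation halves; Wiener first-passage-time
    densities, simulators and derived accumulated-evidence measures; a
    self-contained hierarchical Bayesian drift-diffusion sampler with
    Gelman-Rubin diagnostics, posterior tail probabilities and posterior
    difference-in-differences; neural-covariate-modulated model variants
    compared by the deviance information criterion; and trial- and
    subject-level difference-in-differences regressions with subject-clustered
    robust errors and a two-model correction for logit nonlinearity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    sandwich,
    lmtest,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
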