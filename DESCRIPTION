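Package: avddm
Title: Hierarchical Drift Diffusion Modelling of Multisensory Decision-Making
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying age effects on audiovisual versus unisensory
    perceptual decision-making with hierarchical Bayesian drift diffusion
    models. Provides an exact Wiener first-passage-time likelihood, synthetic
    behavioural-data generation for a three-condition (visual, auditory,
    audiovisual) two-coherence object-categorisation design, robust trial- and
    participant-level preprocessing, Metropolis-within-Gibbs posterior
    sampling over the eight conditional-dependency model variants,
    Gelman-Rubin convergence diagnostics, DIC model selection, posterior
    predictive checks, and derived multisensory-benefit statistics (AV-V
    contrasts, optimal cue combination, measures of inverse effectiveness)
    with age correlations, plus a-priori power computation for multiple
    regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda
Config/testthat/edition: 3
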