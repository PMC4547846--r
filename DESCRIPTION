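Package: pomgrad
Title: Reaction-Diffusion Modelling and Profile Analysis of Buffered Cortical
    Kinase Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model and analyse cortical concentration gradients that
    are buffered by intermolecular (trans) auto-phosphorylation, motivated by
    the Pom1 kinase gradient at fission-yeast cell poles. Provides closed-form
    steady states of the simplified quadratic-decay model and its exponential
    (cis) counterpart, a finite-difference solver for the detailed multi-state
    phosphorylation model and for cluster-based (concentration-dependent
    diffusion) variants, estimation of the effective decay exponent, a
    synthetic generator of paired Pom1/Tea4 cortical intensity profiles, and
    the quantification pipeline: smoothing, amplitude and decay-length
    extraction, batch averaging, inverse-variance-weighted log-log regression,
    ratio analysis and model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    zoo,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
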