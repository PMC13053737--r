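Package: cotwinlgcm
Title: Co-Twin Control Latent Growth Curve Analysis of Functional Aging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying socioeconomic influences on functional aging
    with longitudinal twin data.  Implements construction of a T-scored
    functional aging index from four biomarkers, single-factor scoring of
    financial strain with missing-item tolerance, a two-slope age-based
    latent growth curve model with pair- and individual-level random effects
    fitted by maximum likelihood, between-/within-pair covariate
    decomposition with zygosity-stratified refits, an attenuation-based
    classification of causal versus genetic or shared-environmental
    confounding, and a biometrical (ACE) twin-cohort simulator with
    closed-form expected between/within coefficients that serves as an
    analytic oracle for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
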