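Package: npdim
Title: Latent Neuropsychiatric Dimensions, Trajectories and Risk-Marker Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving latent neuropsychiatric dimensions from ordinal
    questionnaire items and relating them to clinical, imaging and genetic
    markers of neurodegenerative disease risk. Implements an item-preparation
    chain (reverse coding, composite scores, a missingness-threshold
    information-score trade-off, complete-case filtering), exploratory factor
    analysis with minimum-residual extraction and oblimin rotation, cross-group
    factor comparability via orthogonal Procrustes alignment and Tucker
    congruence, regression-method factor-score projection, sliding-window
    Gaussian-kernel conditional trajectories over age and time since diagnosis,
    and covariate-adjusted association models with Bonferroni control. A
    synthetic cohort generator with known ground truth (correlated latent
    factors, group- and time-to-diagnosis-dependent trajectories,
    block-structured missingness, genotype carriers, coupled imaging
    phenotypes) provides a parameter-recovery test surface for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
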