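Package: bsmtools
Title: Bodily Sensation Map Analysis for Object-Affordance Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing Bodily Sensation Map (BSM) click data from
    studies in which participants report increased (activation) or decreased
    (deactivation) sensations on body silhouettes while viewing stimuli.
    Covers ingestion and validation of click-level data with study exclusion
    rules, region-wise signed-log embodiment scoring, kernel-smoothed
    red/blue BSM rendering with flexible filtering, region-of-interest pixel
    quantification, Earth Mover's Distance colour-histogram comparison and
    hierarchical clustering of maps, crossed mixed-effects modelling with
    estimated marginal means and Bonferroni post-hocs, a Yates-corrected
    chi-squared guess analysis, and a full synthetic-study simulator for
    offline testing and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    lme4,
    emmeans,
    png,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
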