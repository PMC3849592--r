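Package: fiberox
Title: Per-Myofiber Quantification of Oxidative Damage in Muscle Histology
Version: 0.1.0
Authors@R: person("Fiberox", "Developers", email = "fiberox@example.org",
    role = c("aut", "cre"))
Description: Quantifies oxidative damage (protein carbonyl groups and
    4-hydroxy-2-nonenal adducts) and cross-sectional area of individual
    myofibers in three-channel fluorescence images of skeletal muscle
    sections. Segments fibers from a membrane (wheat germ agglutinin)
    channel, measures background-corrected per-fiber mean intensities in
    grayscale units on a 12-bit scale, stratifies fibers into
    damage-defined quartile classes, and runs covariate-adjusted cohort
    statistics (ANCOVA, stage trend regression, partial correlation with
    the ankle-brachial index, repeated-measures quartile models). Includes
    a synthetic cohort generator that emulates muscle cross-sections with
    full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    EBImage,
    Rcpp,
    emmeans,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
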