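Package: fawmeta
Title: Meta-Analysis of Temperature Effects on Fall Armyworm Life History
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how temperature, moderated by relative
    humidity and photoperiod, shifts the life-history traits of the fall
    armyworm (Spodoptera frugiperda) from multi-study temperature-gradient
    experiments. Implements log response ratio effect sizes with sampling
    variances, fixed-effects and REML random-effects inverse-variance
    pooling, heterogeneity statistics (Cochran's Q, I-squared, tau-squared),
    moderator meta-regression with the Qt = Qm + Qe partition, per-trait
    subgroup pooling, temperature-response profiles with optimum extraction,
    optimal-condition tables, and publication-bias diagnostics (funnel data,
    Egger's regression test, Rosenthal's fail-safe N). Includes a synthetic
    multi-study data generator with closed-form ground truth for validating
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
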