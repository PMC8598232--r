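Package: urgetach
Title: Tachometric Analysis of Urgent Cognitive Control Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation and resampling inference for tachometric functions
    (proportion correct as a function of raw processing time) from urgent
    two-alternative forced-choice experiments with a response deadline and a
    variable gap between go-signal and target, such as spatial Stroop and
    flanker tasks. Provides a balanced factorial trial-design builder, a
    synthetic trial generator with a logistic accuracy rise and a
    congruency-dependent below-chance dip, locally weighted quadratic
    regression smoothing of binned accuracy, the maximum-drop-below-chance
    statistic and rightward-shift estimate, label-permutation tests for
    congruency and trial-sequence effects, bootstrap standard errors, and an
    end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
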