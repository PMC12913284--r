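Package: centhresh
Title: Central-Threshold Estimation from Ternary-Response Timing Judgments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ternary-response timing-judgment experiments
    in which observers report, for two stimuli separated by a stimulus-onset
    difference d, whether the first appeared before the second, the second
    before the first, or both simultaneously. The task yields two psychometric
    functions whose horizontal distance isolates the threshold of the central
    timing comparator, free of peripheral latency differences. The package
    estimates this central threshold nonparametrically (weighted
    pool-adjacent-violators monotonization followed by the modified
    Spearman-Karber mean) and parametrically (maximum-likelihood fit of a
    two-threshold independent-channels observer model with separate
    successiveness and order thresholds), tests threshold invariance across
    conditions with percentile-bootstrap confidence intervals, estimates
    practice curves, computes group-level paired statistics, and simulates
    synthetic observers with configurable response contamination for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    lhs
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
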