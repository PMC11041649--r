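Package: gazebias
Title: Gaze-Bias Analysis of Covert Attention in Visual Working Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing fixational eye movements as an index of
    covert attention to items held in visual working memory. Provides a
    plain-text reader/writer for 1000 Hz binocular gaze recordings with
    event markers, spline-based blink interpolation, calibration-target
    normalization to a +/-100 unit stimulus frame, epoching with baseline
    correction and trial-exclusion rules, velocity-threshold microsaccade
    detection with toward/away classification, the 'towardness' gaze-bias
    metric, cluster-based sign-flip permutation tests on time courses,
    JZS (Cauchy-prior) Bayes factors for one-sample t-tests with prior
    sensitivity analysis, a noncentral-t power sensitivity solver, and a
    synthetic session generator with ground truth for end-to-end pipeline
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
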