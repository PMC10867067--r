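Package: foragescan
Title: Search Organization Metrics and Choice Models for Dynamic Visual
    Foraging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how observers organize their search in
    dynamic, non-exhaustive visual foraging tasks.  Computes the four
    standard scan-path organization indicators (best-r, mean intertarget
    distance, percentage above the optimal open Hamiltonian path, and the
    intersection rate), fits a sampling-without-replacement target-choice
    model with class-preference, class-stickiness, proximity and
    direction-persistence biases by maximum likelihood, splits trials into
    time bins, and compares candidate linear mixed-effects models of the
    organization scores by AIC/AICc.  Includes a simulator of the
    moving-items foraging task (displays, item motion, forager agents,
    lifespan-style cohorts) so every stage of the pipeline can be exercised
    on synthetic data.
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
    withr
Config/testthat/edition: 3
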