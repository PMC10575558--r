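Package: confarb
Title: Arbitrating Generative Models of Perceptual Confidence in 3AFC Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates four generative observer models of three-alternative
    forced-choice (3AFC) decisions and confidence ratings (a marginalizing
    Bayesian ideal observer, a hierarchical Bayesian observer, a 3-point
    Bayesian ideal observer, and the response-congruent-evidence heuristic),
    locates stimulus conditions where the models' z-scored confidence
    predictions maximally diverge (summed pairwise Cohen's d over a 3-D
    stimulus-strength grid), fits a per-observer internal-noise scalar by
    type-1 cross entropy, scores each model's confidence predictions by type-2
    cross entropy against kernel-density smoothed confidence distributions
    conditioned on choice category, and quantifies model recoverability with
    synthetic observer cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
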