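Package: somnarch
Title: Sleep Architecture and Hyperarousal Features from Polysomnography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies EEG correlates of hyperarousal in chronic insomnia
    from polysomnography: first-order Markov sleep-wake transition
    probabilities, multitaper relative spectral band power per sleep stage,
    sleep-spindle and slow-oscillation coupling features, and a wake-EEG
    similarity index (WESI) scored by a logistic classifier on logit
    z-scored relative band powers. Includes a synthetic-cohort generator
    with injectable placebo-corrected treatment effects, and a statistical
    layer of linear mixed models, hurdle models for sparse transition
    counts, likelihood-ratio tests with false-discovery-rate control, and
    treatment contrasts with Wald confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
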