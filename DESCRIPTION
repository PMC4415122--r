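Package: comdecode
Title: Moment-by-Moment Decoding of Choice and Change-of-Mind Detection
    from Motor-Cortical Population Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Single-trial readout of upcoming reach choice from simultaneously
    recorded premotor and motor cortical populations. Binned spike counts are
    smoothed into low-dimensional latent trajectories by Gaussian-process
    factor analysis, a time-invariant wide-margin linear classifier trained on
    forced-choice trials yields a graded, normalized decoded-choice trace for
    every trial, and a conservative likelihood-ratio detector flags covert
    changes of mind. A synthetic inhomogeneous-Poisson session generator with
    ground-truth internal events (vacillation, induced switches, hesitation,
    indecision) and a battery of downstream behavioral and statistical
    analyses (PSTH similarity, baseline-distance, crossing-window firing
    rates, reaction-time contrasts, indecision regression, split-array
    agreement) complete the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
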