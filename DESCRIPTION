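Package: cohfo
Title: Coincident High-Frequency Oscillation Burst Analysis for Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and analysis of coincident high-frequency oscillation
    (HFO) bursts in multichannel intracranial EEG recorded during verbal
    memory tasks. Implements a logarithmically spaced filter-bank burst
    detector (Hilbert envelope, sliding z-score, dual thresholds, cycle
    verification, frequency-span specificity filtering), peri-event raster
    and coincidence analysis with correlation-based channel classification,
    hierarchical clustering of co-bursting networks with temporal-jitter
    surrogate controls and bootstrap stability (Adjusted Rand Index), a
    per-bin linear mixed-effects testing layer with false-discovery-rate
    correction, anatomical summaries, and a synthetic local-field-potential
    generator with known ground truth for end-to-end validation.
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
    lme4,
    lmerTest,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    ape,
    cluster,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
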