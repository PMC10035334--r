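Package: spindlefusion
Title: Hierarchical Fusion Detection of Sleep Spindles in Single-Channel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects sleep spindles (11-16 Hz oscillatory bursts during NREM
    stage-2 sleep) in single-channel EEG with a two-layer fusion algorithm: a
    complex Morlet wavelet envelope detector and a sliding-window RMS detector
    form the first layer, and their non-coincident detections are filtered in a
    second layer by local-outlier-factor pruning followed by k-means clustering
    on event amplitude, discarding the extreme-amplitude clusters. Includes
    event-level evaluation against expert consensus (precision, recall,
    specificity, accuracy, F1), a cohort report generator, and a synthetic EEG
    simulator (1/f background plus Hann-windowed sigma-band bursts with noisy
    simulated expert annotations) so the full pipeline is testable without
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
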