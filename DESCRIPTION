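Package: rippleRT
Title: Spectrotemporal Ripple Reaction-Time Synthesis and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reaction-time based assessment of auditory spectrotemporal
    sensitivity. Synthesizes calibrated spectrotemporal ripple-in-noise stimuli
    (pink-noise carriers with band accentuation and sinusoidal spectrotemporal
    modulation), simulates cohorts of LATER-model listeners responding under two
    delivery implementations, and runs the full reaction-time analysis chain:
    censoring and fast-guess removal, block pooling, technical-delay estimation,
    reciprobit construction with censoring-aware LATER fits, BCa-bootstrapped
    effect sizes, modulation transfer functions, adaptive matrix speech-in-noise
    threshold simulation, and correlation and regression analyses linking ripple
    sensitivity to speech-in-noise thresholds.
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
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    boot,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
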