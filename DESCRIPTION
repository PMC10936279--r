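Package: twitchtdi
Title: Tissue Doppler Analysis of Electrically Stimulated Muscle Twitches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for pulsed-wave tissue Doppler
    imaging (TDI) of electrically stimulated isometric muscle twitches.
    Generates scatterer-phantom radio-frequency scanline series under
    prescribed twitch kinematics and fatigue-recovery schedules, estimates
    tissue velocity fields by lag-one phase autocorrelation, segments the
    depth-averaged twitch velocity waveform into onset, zero-crossing and
    end points, extracts five fatigue-sensitive waveform features (peak
    velocity, time-to-zero, total duration, peak velocity-time integral,
    peak strain rate), and reproduces the downstream statistics: baseline
    normalization, paired tests with Holm-Bonferroni correction,
    repeated-measures ANOVA, power-law recovery trend fits, and per-subject
    stepwise regression of twitch torque on waveform features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
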