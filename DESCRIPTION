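Package: neurodyn
Title: Team Neurodynamic Information Modeling from EEG Symbol Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transforms multi-channel EEG band power into per-second ternary
    symbol streams, quantifies persistent neural organization as sliding-window
    Shannon information (neurodynamic information, in bits), and estimates the
    frequency, magnitude and duration of uncertainty-linked information peaks
    at team, member, sensor and 1-Hz frequency resolution.  Includes Welch
    power spectral density estimation on a per-second cadence, equal-occupancy
    ternary symbolization, composite team symbol construction, randomized
    (surrogate) baselines for plug-in entropy bias, the team/member shared
    information decomposition, numeric EEG power-value traces and their
    correlation with information, prominence-based peak detection with
    half-prominence durations, and a synthetic-data generator with planted
    ground-truth epochs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
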