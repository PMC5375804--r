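Package: pulsetherm
Title: Pulse-Phase Thermography Analysis for Cotton Foreign-Matter Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of pulsed-thermography experiments for
    detecting and identifying foreign matter in cotton lint. Provides a
    lumped-capacitance synthetic thermal-video generator, a bit-exact binary
    video container, Otsu and center-region segmentation, pulse-phase
    (temporal Fourier) and waveform feature extraction with phasegram and
    ampligram rendering, pairwise Hotelling T-squared tests and canonical
    discriminant analysis, and leave-one-out cross-validated LDA and SVM
    classification for the two-class detection and twelve-class
    identification tasks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    generics,
    jsonlite,
    readr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
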