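Package: ammod
Title: Amplitude-Modulated Music, Neural Entrainment and Sustained Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how amplitude modulation (AM) in background
    music relates to neural entrainment and sustained attention. Implements
    cochleagram-based modulation-spectrum analysis of audio, parametric
    insertion of rate- and depth-controlled AM into music with a calibrated
    depth metric and stimulus validation, stimulus-brain phase-locking value
    (PLV) spectra for EEG with channel-wise FDR-corrected early/late
    contrasts, and signal-detection scoring of Sustained Attention to
    Response Task (SART) logs with condition-by-block-by-attentional-
    difficulty contrasts. Includes seeded generators for music-like audio,
    pink noise, envelope-entrained EEG and simulated SART cohorts so every
    analysis can be exercised end to end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
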