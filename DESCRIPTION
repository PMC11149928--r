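Package: ripplepac
Title: Sharp-Wave-Ripple Detection and Theta-Gamma Phase-Amplitude
    Coupling for Local Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for hippocampal local field potential (LFP)
    analysis: zero-phase band filtering and 60 Hz notch, Hilbert envelope
    and phase extraction, sharp-wave-ripple (SWR) event detection on the
    z-scored ripple-band envelope with per-event features (peak, duration,
    integral) and baseline normalization, and theta-gamma phase-amplitude
    coupling quantified by the entropy-based Modulation Index. Includes a
    synthetic LFP generator (1/f background, injected ripple bursts of
    controlled z-amplitude, theta-modulated gamma) that provides ground
    truth for end-to-end validation, plus a session/cohort orchestrator
    that emits mixed-model-ready tidy tables.
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
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
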