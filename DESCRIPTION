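Package: vemg
Title: Voluntary EMG Extraction and Proportional Control Under
    Functional Electrical Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Software-only extraction of voluntary surface EMG recorded
    from muscles while they receive functional electrical stimulation
    (FES). Implements a feedforward comb filter with notches at the
    stimulation frequency and its harmonics, and a frame-based adaptive
    least-squares filter that predicts the periodic stimulation and
    m-wave artifacts from previous recording frames and subtracts them,
    leaving the voluntary EMG. Includes a synthetic-recording generator
    (band-limited Gaussian voluntary EMG contaminated by one-sample
    stimulation pulses, an m-wave train with randomized amplitude and
    time constant, and optional amplifier saturation), filter
    characterization (equivalent FIR, frequency and phase response,
    group delay, effective end-to-end delay), evaluation metrics
    (muscle response index, power reductions, Welch magnitude-squared
    coherence with an analytic confidence limit), and the proportional
    EMG-to-pulsewidth control chain with slew-rate-limited smoothing
    used in closed-loop neurorehabilitation systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
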