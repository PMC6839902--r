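Package: optoephys
Title: Analysis of Optogenetically Evoked LFP Entrainment, Intrinsic
    Properties, and Recognition-Memory Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A pipeline for quantifying the effects of optogenetic
    stimulation of hippocampal long-range inhibitory neurons.  Provides
    multitaper spectral estimation (Slepian tapers, trial-averaged power
    and coherence, moving-window spectrograms, theta/delta state
    detection), alignment and quality control of light-evoked LFP trials,
    percent-change measures of power and coherence at the stimulation
    frequency, current-clamp intrinsic-property extraction (threshold,
    half-width, adaptation, interspike-interval variability, persistent
    firing, input resistance), light-evoked postsynaptic-current
    classification, and discrimination-index scoring of object and odor
    recognition-memory sessions.  A synthetic-data generator with full
    ground truth stands in for raw recordings, so every stage of the
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
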