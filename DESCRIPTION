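Package: rhythmtrack
Title: Neural Tracking of Auditory Rhythms for Evaluation of Disorders of
    Consciousness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying cortical tracking of auditory rhythms in
    multi-channel EEG and relating it to clinical state in disorders of
    consciousness. Computes cerebro-acoustic phase coherence between stimulus
    modulations (a 41 Hz amplitude-modulated, 2 Hz frequency-modulated tone,
    or a natural-speech envelope) and EEG in 2-second analysis bins, including
    its inter-trial phase coherence reduction for periodic stimuli, signed
    response topographies, and centro-frontal band features. Provides a
    resampling chance-level null over non-integer frequencies, bootstrap group
    comparisons, Rayleigh tests, clinical-score correlations with
    false-discovery-rate control, and an RBF-kernel support-vector-machine
    protocol for diagnosis (minimally conscious state versus unresponsive
    wakefulness syndrome) and prognosis classification. A synthetic-cohort
    generator with a von Mises phase-jitter model produces stimuli,
    phase-locked EEG, and clinical metadata with known ground truth so the
    entire pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
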