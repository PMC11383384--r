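Package: sniffsync
Title: Linking Respiration to Brain State in Freely Moving Mice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for synchronized thoracic-pressure respiration,
    EEG and EMG recordings from freely moving mice. Provides autocorrelation
    based sniff-frequency estimation, inhalation-peak detection,
    event-aligned respiration dynamics, rule-based wake/NREM/REM scoring,
    sine-taper multitaper spectral matrices with shrinkage regularization,
    evolving partial coherence between respiration and cortical rhythms with
    null p-values and FDR control, event-locked lagged regression, weighted
    connectivity graphs, EMG-movement classification, and a synthetic-session
    generator with exported ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    lme4,
    lmerTest,
    signal,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
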