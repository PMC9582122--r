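Package: narrband
Title: Broadband Spectral Encoding and Directed Connectivity for Visual-Narrative iEEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for intracranial local field
    potential (sEEG) experiments contrasting sequential versus scrambled image
    narratives. Provides a synthetic multi-subject LFP generator with known
    region- and condition-specific broadband effects and directed coupling,
    common-average referencing and peri-transition epoching, single-trial Welch
    power spectra on a fixed 2-100 Hz grid with line-noise bins removed,
    pooled and leave-one-subject-out PCA of normalized spectra, a
    condition-indicator encoding model with Monte-Carlo cross-validation and a
    label-permutation null, a correlation-matching population decoder, and
    pairwise autoregressive Granger-causality network contrasts with
    contingency-table statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    MASS,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    lmtest,
    optparse
Config/testthat/edition: 3
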