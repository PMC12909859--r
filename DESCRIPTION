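Package: dyadsync
Title: Dual-EEG Inter-Brain Phase Synchrony for Parent-Infant Hyperscanning
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-person (hyperscanning) EEG recordings of
    parent-infant dyads observed under a five-phase smartphone-adapted
    Still-Face Paradigm. Computes cross-brain phase synchrony with the weighted
    Phase Lag Index (wPLI) from band-limited Hilbert phases on 2-second
    hyper-epochs, validates every channel-pair value against a 200-permutation
    surrogate null, aggregates trial-averaged and global synchrony per dyad,
    condition and frequency band, and reproduces the nonparametric inferential
    chain (Friedman omnibus, pairwise Wilcoxon signed-rank post hocs with
    Benjamini-Hochberg correction, covariate screening, region-level one-sided
    still-face contrasts). Includes a seeded synthetic dyad generator with
    known ground-truth cross-brain coupling so every pipeline stage is testable
    without raw EEG, and minimal EDF/BDF readers and writers for time-locked
    dual recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
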