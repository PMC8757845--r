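Package: pvascore
Title: Automatic Scoring of Patient-Ventilator Asynchrony from Pressure and Flow Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and scores patient-ventilator asynchrony events
    (ineffective efforts, auto-triggering, double-triggering, backup cycles)
    during pressure support ventilation from airway-pressure and flow
    waveforms. Includes per-cycle leak estimation with a discard rule for
    excessively leaky or turbulent cycles, the asynchrony index, a synthetic
    pressure-support-ventilation waveform simulator with exact ground-truth
    annotations for validation, and inter-rater agreement statistics
    (sensitivity, specificity, positive predictive value, Cohen's kappa,
    agreement) for comparing scorings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
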