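Package: sparsecode
Title: Psychophysics and Sparse Population Decoding for 2AFC Orientation
    Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for linking two-alternative forced-choice (2AFC)
    orientation-discrimination behaviour in the mouse to sparse population
    codes in primary visual cortex. Fits logistic-with-lapse psychometric
    functions by constrained maximum a posteriori estimation and Markov
    chain Monte Carlo, extracts threshold and total integration times with
    credible intervals, and builds balanced average subjects. Decodes
    stimulus orientation from single-unit and population spike counts with
    a repeated-split logistic-regression protocol and a consistency
    criterion, characterises orientation tuning (vector-sum selectivity
    with jackknife errors), waveform classes and arousal states, and
    estimates via virtual-population resampling how many unreliable
    neurons must be pooled to match behavioural performance, including
    within-condition shuffle controls and sensory versus cognitive noise
    models. A seeded synthetic-data module generates behavioural trial
    streams and sparse orientation-tuned Poisson spike counts so the whole
    pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
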