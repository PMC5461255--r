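Package: vocopred
Title: Predicting Noise-Vocoded Speech Intelligibility from a Cognitive Test Battery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying which cognitive abilities predict the
    intelligibility of noise-vocoded (cochlear-implant simulated) speech.
    Provides a seeded channel vocoder with WAV input/output, open-set
    sentence scoring and learning curves, derivation of thirteen canonical
    predictor variables from raw cognitive test records, a from-scratch
    single-response partial least squares (PLS) regression with variable
    importance in projection (VIP) scores, and a two-step inference engine
    that nests VIP-based variable selection inside leave-one-out
    cross-validation with permutation tests of component significance.
    A calibrated synthetic battery generator emulates the two-age-group
    study design so the whole pipeline is testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
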