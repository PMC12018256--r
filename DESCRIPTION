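Package: tfodetect
Title: Transabdominal Fetal Pulse Oximetry Signal Processing and Hypoxemia Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing chain for transabdominal fetal pulse oximetry (TFO):
    demodulation of frequency-multiplexed dual-wavelength detector recordings,
    lower-envelope DC and lock-in AC extraction referenced to the fetal heart
    rate, pulsation and modulation (ratio-of-ratios) features under the
    modified Beer-Lambert law, a two-head multilayer perceptron that fuses
    information across detectors into a binary fetal hypoxemia decision, and
    a staggered round-based five-fold cross-validation harness with
    window-overlap exclusion. Includes a synthetic mixed-photoplethysmogram
    generator that emulates controlled fetal de-saturation experiments so the
    full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
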