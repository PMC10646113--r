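Package: skeletime
Title: Circadian Rhythm Analysis of Mechanically and Osmotically Reset Skeletal Tissue Clocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis workflow for circadian clock resetting in
    skeletal tissues (articular cartilage and intervertebral disc). Provides a
    Poincare limit-cycle oscillator ensemble generator with dose-calibrated
    mechanical-loading and hyperosmolarity stimuli, moving-average detrending,
    cosinor and damped-cosinor rhythmometry with zero-amplitude and permutation
    tests, phase-shift and amplitude quantification of stimulus responses,
    phase-response and phase-transition curves with winding-number resetting
    classification, single-cell responder calling, and rhythmic-gene detection
    on negative-binomial count time series with Benjamini-Hochberg tiers,
    differential response testing and circadian phase projection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
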