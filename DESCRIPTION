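Package: slowosc
Title: Detection and Classification Tools for Cortical Slow Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for cortical slow-oscillation recordings:
    dynamic-threshold upstate detection in vivo (delta-band local field
    potential plus population-spiking confirmation) and in vitro (coincident
    two-signal detection on membrane potential and gamma-band envelope),
    spike-unit quality control and trough-to-peak waveform classification,
    drug-response ("activated") unit classification, cross-correlogram
    screening and consecutive-bin inhibitory-connection detection, and
    PCA plus Gaussian-mixture electrophysiological cell typing. Includes a
    synthetic-recording generator with full ground truth so every stage can
    be validated without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    mclust,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
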