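Package: greenlight
Title: Artificial Light Management for Plant Development in Controlled
    Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing artificial light schedules for plant growth
    facilities. A six-parameter periodic light waveform (period, photoperiod,
    phase of dawn, twilight duration, amplitude and offset) drives an
    entrainable circadian gene-network model whose FT and ATHB2 outputs are
    converted to days-to-flower and hypocotyl length. Single-property and
    two-stage collective sweeps over the light properties identify regimes
    that accelerate flowering, keep seedlings compact, and minimise LED
    driver energy consumption.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
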