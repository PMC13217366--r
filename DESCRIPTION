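Package: cirispec
Title: Messenger-Tagging Cryogenic Infrared Ion Spectroscopy Processing and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processing pipeline for messenger-tagging (cryogenic) infrared action
    spectroscopy on an ion mobility time-of-flight mass spectrometer, together with
    a forward instrument simulator. Converts paired laser-on/laser-off time-of-flight
    transients into calibrated mass spectra, extracts N2-tag series, bins and slices
    ion-mobility arrival-time distributions, and retrieves relative absorption
    cross-section spectra via tag-depletion linearization and photon-flux
    normalization. The simulator reproduces the trap cycle, Poisson N2 tagging,
    two-component mobilograms and wavelength-dependent tag depletion, providing
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
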