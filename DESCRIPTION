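Package: odormvm
Title: Modified Vector Model for Odor Intensity of Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the perceived odor intensity (OI) of single odorants and
    their binary/ternary mixtures directly from gas-phase concentrations using
    a modified vector model: component intensities follow a family-specific
    log-linear psychophysical law in the odor activity value (OAV = C/C_Thr),
    and mixture intensity is the vector sum of component intensities with a
    single family-wide interaction coefficient cos(alpha) derived from the
    slope of the mixture-versus-summed-intensity relation. Includes the
    calibration routines that fit the law and the mixture slope from sensory
    panel data, an electronic-nose style pipeline (sensor signals ->
    concentration estimation by a feedforward neural network -> mixture OI),
    a built-in odorant registry with measured odor thresholds, and seeded
    synthetic-data generators for panel ratings and multi-sensor responses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
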