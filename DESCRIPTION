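Package: turbidr
Title: Fixed-Vial Optical Density Calibration and Turbidostat Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computational toolkit for long-term continuous culture on
    multiplexed turbidostat platforms. Implements a fixed-vial optical
    density (OD) calibration workflow (inoculation planning, stock-OD
    back-calculation, calibration correction, monotone sigmoid curve
    fitting, LED-power selection, temperature calibration), a
    delta-raw OD engine that is immune to additive glass-vial offsets,
    threshold-triggered dilution control with growth-rate estimation,
    mid-experiment vial replacement with calibration-blank reset, and
    media-bottle accounting with consumption forecasting and alerting.
    A deterministic virtual rig (optics, vials, cultures, pumps)
    provides ground truth so every component can be exercised and
    validated end-to-end without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
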