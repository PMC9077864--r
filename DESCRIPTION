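Package: clodr
Title: Scan Analysis and Simulation for Contact Lens-Type Ocular Dosimeters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for flatbed-scanner dosimetry of curved contact lens-type
    ocular dosimeters (CLODs). Implements the full analysis chain from scanned
    16-bit TIFF pixel values to net optical density (netOD), power-law
    dose-response and calibration fitting, analytic sensitivity, and a
    decomposed dose-uncertainty budget separating scan-noise and fit-parameter
    contributions. Includes comparison metrics for scan modes and
    index-matching compensating materials (dose-difference accuracy,
    sensitivity ratios, scan-uniformity coefficients of variation) and a
    physics-based synthetic scan generator that models dose-dependent
    darkening, mode- and material-dependent gain and noise, and the
    Newton's-ring interference artifact produced by the air gap between a
    curved dosimeter and the scanner glass.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
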