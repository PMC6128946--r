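Package: arthronirs
Title: Arthroscopic Near Infrared Spectroscopy Calibration for Cartilage
    and Subchondral Bone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibration pipeline for predicting articular cartilage
    biomechanics and subchondral bone structure from arthroscopic and in
    vitro near infrared (NIR) spectra. Provides a synthetic equine
    (pony) cartilage-repair study generator with known ground truth,
    Savitzky-Golay spectral preprocessing with a contact-quality area
    statistic for probe-contact outlier rejection, Levenberg-Marquardt
    training of single-hidden-layer (tanh/linear) regression networks
    with validation-based early stopping, greedy forward wavelength
    selection, NRMSE and RPIQ model evaluation with nonparametric group
    statistics, and an indentation-mechanics module deriving equilibrium
    and dynamic moduli from stress-relaxation records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    minpack.lm,
    optparse
Config/testthat/edition: 3
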