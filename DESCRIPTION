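Package: thermoseedr
Title: Induction-Coil Calorimetry Simulation and SAR Estimation for
    Magnetic Scaffold Hyperthermia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator and estimation pipeline for calorimetric
    characterization of magnetic scaffold (MagS) thermoseeds used in
    interstitial hyperthermia. Computes the magnetic flux-density map of a
    single-layer induction coil by Biot-Savart superposition of filamentary
    loops, converts local field amplitude into hysteresis and dielectric/eddy
    heating power through sampled or parametric BH loops, solves the transient
    heat equation on a voxelized scaffold-phantom scene with a convective
    (Robin) air boundary and field on/off switching, and estimates the
    specific absorption rate (SAR) from multi-probe temperature records by
    the initial-slope and corrected-slope methods. Includes axial and radial
    sample-misplacement sensitivity sweeps, a field-homogeneity metric,
    Faraday pickup-coil calibration, and seeded synthetic-data generators for
    BH loops, temperature logs and probe-coil EMF readings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
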