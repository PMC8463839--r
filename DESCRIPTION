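Package: laminarbeta
Title: Laminar Dynamics of Transient Beta Bursts from MEG Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for temporally resolved laminar
    inference on transient beta bursts in MEG. Builds paired pial/white-matter
    cortical patch geometries with cortical-column (link-vector) dipole
    orientations, computes closed-form current-dipole fields in a spherical
    conductor, simulates layer-specific burst dipole time courses (a
    phenomenological proximal/distal drive surrogate and a simplified Gaussian
    model), injects calibrated white or pink sensor noise, detects and aligns
    beta bursts (Butterworth/Hilbert envelope thresholding, adaptive Woody
    filter), and compares deep versus superficial generative models with a
    sliding-window restricted-maximum-likelihood free-energy comparison.
    Includes scripted validation experiments: SNR sweeps, co-registration
    error sweeps, an alternative-model battery, and spatial/temporal shuffle
    controls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
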