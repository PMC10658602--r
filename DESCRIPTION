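Package: pacranial
Title: Transcranial Photoacoustic Propagation, Ultrasound Sensor Models and
    Planar Tomographic Reconstruction
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying photoacoustic (PA) sensing and imaging through
    human skull bone. Provides synthetic three-layer cranial bone phantoms
    (cortical tables and porous diploe), a k-space pseudospectral solver for
    longitudinal acoustic wave propagation in heterogeneous lossy media (1D,
    2D, axisymmetric and 3D), frequency-domain analysis of skull insertion
    loss, transfer-matrix models of Fabry-Perot type optical ultrasound
    sensors and piezoelectric transducers, noise-equivalent pressure
    estimation, and FFT-based reconstruction of initial-pressure volumes from
    planar sensor scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    signal,
    jsonlite,
    yaml,
    tiff,
    RNifti,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
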