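Package: pyrofield
Title: Landau-Devonshire Thermodynamics and Phase-Field Modelling of
    Pyroelectric Ferroelectric Nanocatalysts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale computational models for Zr-doped barium titanate
    pyroelectric nanocatalysts: temperature-dependent Landau-Devonshire
    free-energy analysis (spontaneous polarization curves, phase stability,
    pyroelectric coefficient dPs/dT, polarization-rotation energy barriers),
    a semi-implicit Fourier-spectral time-dependent Ginzburg-Landau (TDGL)
    phase-field solver on periodic 2D/3D grids with gradient, electrostatic,
    elastic and random-defect-field contributions plus a hysteresis-loop
    protocol, classification of polarization fields into tetragonal,
    orthorhombic and rhombohedral variants, a lumped photothermal
    heating/cooling and pyroelectric device-response model, and band
    alignment on the NHE scale with reactive-oxygen-species half-reaction
    feasibility and Tauc bandgap extraction. Seeded synthetic-fixture
    generators provide every input the pipeline needs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
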