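Package: memprofiler
Title: Transversal and Lateral Analysis of Lipid Bilayer Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Membrane analysis toolkit for bilayer particle configurations:
    transversal profiles (mass and charge density, electrostatic potential by
    double integration of the Poisson equation, Boltzmann-inversion potential
    of mean force, solute dipole orientation), Irving-Kirkwood lateral
    pressure profiles with per-monolayer integral moments and conformational
    work, lateral structure (deuterium order parameters, periodic Voronoi
    tessellation, transbilayer thickness maps, domain radial profiles,
    solute proximity statistics), and solute kinetics (interleaflet crossing
    rates, interfacial confinement, lateral diffusivity). Includes a
    synthetic bilayer emulator with full parameter control and recorded
    ground truth, plain-text GRO/PDB/profile I/O, and a YAML-driven pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    pracma,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
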