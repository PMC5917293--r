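Package: mdtsim
Title: Lattice-Boltzmann Simulation of Magnetic Drug Targeting in Vessels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A desk-scale simulator for magnetically steered paramagnetic
    nanoparticles suspended in blood flow. Couples a forced D3Q19
    lattice-Bhatnagar-Gross-Krook (LBGK) solver with Bouzidi-Firdaouss-
    Lallemand curved-wall boundaries and pulsatile parabolic inlets to an
    overdamped Lagrangian point-particle model with magnet-dipole forcing,
    induced inter-particle dipolar interactions, wall and pair lubrication
    closures, gravity/buoyancy and Brownian noise. Ships synthetic voxelized
    vessel fixtures (straight cylinder, curved tube), a voxel-mask file
    format, region-of-interest targeting-efficiency readouts, and validation
    drivers for lubrication, dipolar forces and Poiseuille hydrodynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
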