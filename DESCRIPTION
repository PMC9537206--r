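Package: stenoflow
Title: Pulsatile Non-Newtonian Hemodynamics in Idealized Stenosed Vessels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational hemodynamics pipeline for arterial
    stenosis studies. Simulates unsteady incompressible axisymmetric blood
    flow with Carreau-Yasuda shear-thinning rheology through an idealized
    stenosed vessel using a staggered finite-volume projection solver
    (BDF2 time stepping, Picard-lagged viscosity), driven by synthetic
    pulsatile inlet-velocity and outlet-pressure waveforms. Post-processes
    the wall shear stress into time-averaged wall shear stress (TAWSS),
    oscillatory shear index (OSI) and relative residence time (RRT), and
    orchestrates cross-severity sweeps (healthy plus 25/35/50/65% area
    stenosis) with analytic Poiseuille and Womersley oracles for
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
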