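Package: azotraj
Title: Trajectory-Ensemble Analysis for Azobenzene Photoswitch Surface-Hopping Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyze ensembles of nonadiabatic surface-hopping
    trajectories of azobenzene-based photoswitches such as azo-escitalopram.
    Provides extended-XYZ/energy-table trajectory I/O, internal-coordinate
    (CNNC/CCNC/CCCC dihedral, CNN/NNC angle) measurement and Z-matrix-style
    fragment construction, a synthetic trajectory-ensemble generator with
    configurable excited-state kinetics, energy-conservation quality control,
    classical adiabatic population curves with delayed-exponential and
    sequential two-step kinetic fits, photoisomerization quantum yields and
    cis-conformer fractions with binomial uncertainties, rotation-versus-
    inversion hop-mechanism classification, geometric hydrogen-bond analysis,
    ensemble absorption spectra with excitation-window initial-condition
    sampling, and an end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
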