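Package: peptherm
Title: Peptide Dimerization Thermodynamics from Variable-Temperature
    Native MS and Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("peptherm", "developers", email = "peptherm@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of osmolyte-modulated peptide
    self-assembly observed by native mass spectrometry and molecular
    simulation. Computes apparent association constants from ion
    intensities, fits single- and two-regime van't Hoff models with
    data-driven breakpoint selection and derives enthalpy, entropy and
    free energy with replicate uncertainties; builds Boltzmann-inversion
    free-energy profiles with block-bootstrap variance bands from
    centre-of-mass distance trajectories, classifies dimer, transition
    and monomer states, counts hydrogen bonds and computes radial
    distribution functions; and quantifies oligomer abundances and a
    degree-of-oligomerization statistic from centroided peak lists.
    Seeded synthetic-data generators (two-regime intensity tables,
    overdamped Langevin trajectories on known potentials, hydrogen-bond
    micro-geometries, ideal-gas coordinate sets, Gaussian peak lists)
    stand in for the instrument and the simulation engine so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
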