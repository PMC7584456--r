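Package: kda
Title: Restraint-Guided Docking and Interface Analysis for KCNQ1-KCNE
    Channel Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and validating models of voltage-gated
    potassium channel complexes formed by KCNQ1 and KCNE auxiliary
    subunits. Implements state-dependent crosslink distance restraints
    with harmonic violation scoring, an iterative restraint-guided
    rigid-body docking protocol with score gating, clustering and C2
    symmetrization to 4:2 complexes, interface contact and
    solvent-accessibility (Shrake-Rupley) analysis with a
    helical-rotation null model for orientation validation,
    trajectory-based dynamical-network and allosteric-pathway analysis,
    pore-radius profiling, and electrophysiology fitting (Boltzmann
    activation curves, exponential gating kinetics, double-mutant-cycle
    coupling energies). Synthetic-data generators with known ground
    truth make every stage testable without external structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
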