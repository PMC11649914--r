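Package: symportkit
Title: Kinetics and Simulation Analytics for Proton-Coupled Symport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing proton-coupled membrane symporters of the
    major facilitator superfamily, built around an eight-state alternating
    access transport cycle with 2 H+ : 1 substrate stoichiometry. Implements a
    thermodynamically consistent kinetic cycle model with simulated
    solid-supported membrane electrophysiology (SSME) readout; SSME trace
    analysis (peak currents, exponential decays, apparent pKa fits,
    induced-fit kinetics, charge integration, reversal-assay stoichiometry);
    trajectory order parameters, hydration profiles, water-occupancy maps and
    gromos clustering; Gaussian-smeared Ewald electrostatic potential grids;
    a Markov state model pipeline (tICA, reversible maximum-likelihood
    estimation, implied timescales, Chapman-Kolmogorov test, PCCA+); and
    free-energy estimators (well-tempered metadynamics with time-dependent
    reweighting, blue-moon thermodynamic integration). Synthetic-data
    generators (Langevin sampling on toy potentials, lifted feature spaces,
    simulated SSME datasets, toy solvated configurations) make every analysis
    exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    pracma,
    bio3d,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
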