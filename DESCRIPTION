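Package: contpka
Title: Continuum-Electrostatics Calculation of Protein pKa Values and
    Hydrogen-Bond Network Rearrangements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes state-dependent pKa values of coupled titratable sites
    in proteins from PDB structures by solving the linearized
    Poisson-Boltzmann equation on focused finite-difference grids,
    sampling protonation microstates by Metropolis Monte Carlo with
    bias-potential titration, and decomposing pKa shifts into per-residue
    side-chain and backbone contributions.  Includes alternate-conformer
    handling, deterministic polar-hydrogen placement, hydrogen-bond
    network analysis, Nernst treatment of redox-active groups, and
    synthetic structure generators with analytic expectations for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
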