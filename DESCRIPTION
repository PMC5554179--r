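Package: hydrosorb
Title: Coarse-Grained Simulation and Analysis of Water Sorption in Protein-Like Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Desk-scale coarse-grained Monte Carlo engine for simulating water
    adsorption and desorption isotherms of amorphous protein-like bead matrices.
    Water molecules are inserted by continuous lambda-coupling with a soft-core
    potential and removed by Boltzmann-weighted selection; chemical potentials
    are estimated by Bennett's acceptance ratio from test insertions and
    deletions and converted to relative humidity. Matrix rigidity (non-local
    harmonic crosslinks, a disulfide analog) and chain connectivity (a peptide
    backbone analog) are exposed as model knobs. A hydration-structure analysis
    suite provides Shrake-Rupley solvent-accessible surface area, radius of
    gyration, inter-residue shortest-distance maps, water-cluster percolation
    with spanning-network detection, hydration-shell count distributions, radial
    distribution functions, and block-averaged error estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
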