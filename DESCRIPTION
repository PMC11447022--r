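Package: gamdr
Title: Gaussian Accelerated Molecular Dynamics on Toy Energy Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of Gaussian accelerated molecular
    dynamics (GaMD): the harmonic boost potential, automatic determination of
    the boost parameters from collected potential statistics, the dual-boost
    protocol on systems with a separable torsional energy term, and recovery
    of unbiased free-energy landscapes by second-order cumulant reweighting.
    Includes a Langevin (BAOAB) integrator with a staged simulation protocol
    over analytic one- and two-dimensional potentials and small bead-chain
    models, trajectory analyses (named-pair distances, RMSD, RMSF,
    hierarchical RMSD clustering, 1D/2D free-energy profiles), and static
    structural-comparison metrics (Kabsch superposition, matched C-alpha
    RMSD, atom displacement, salt bridges, domain rotation, interface
    contacts) on PDB/mmCIF coordinate files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
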