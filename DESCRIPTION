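Package: hiclattice
Title: Lattice-Based 3D Chromosome Reconstruction from Hi-C with
    X-Inactivation Time-Course Interpolation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs three-dimensional chromosome structures from Hi-C
    contact matrices by simulated annealing of a bead chain on a cubic
    lattice with Metropolis-Hastings acceptance. Zero contacts are imputed
    with a 2D Gaussian kernel over sequentially neighbouring bead pairs,
    contacts are converted to target distances via the classic c^(-1/3)
    power law and normalised to the lattice diagonal, and coarse structures
    are refined to higher resolution by bead insertion and low-temperature
    annealing. Ensembles of independent reconstructions are ranked by
    Q-score (mean pairwise TM-score) and validated by the Pearson
    correlation between target and realised distance matrices. Given Xist
    RAP localisation tracks at successive time points, constant-velocity
    and constant-acceleration kinematic models interpolate per-pair target
    distances at intermediate stages of X-chromosome inactivation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
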