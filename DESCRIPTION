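Package: dmcpull
Title: Pulling-Trajectory Analysis and Coarse-Grained Simulation of DNA
    Mechanocapsules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing steered pulling simulations of tetrahedral
    DNA nanostructures (DNA mechanocapsules). Reads and writes classic
    oxDNA topology and configuration/trajectory files, reconstructs
    force-extension curves from dual harmonic-trap protocols, detects
    rupture forces, computes base-pair denaturation and fluorophore-quencher
    distance series, and measures pore geometry of the four tetrahedron
    faces via triangle incircle radii. Includes a simplified bead-per-
    nucleotide Langevin simulator with breakable base-pair bonds that emits
    oxDNA-format trajectories, and calibration formulas for molecular
    tension-probe assays (quenching efficiency, F-factor, supported lipid
    bilayer density calibration, probe spacing, decay half-life).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
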