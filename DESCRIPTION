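Package: latticefold
Title: Bond-Fluctuation Lattice Monte Carlo of Coarse-Grained Protein
    Thermal Response
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coarse-grained simulation of a single protein chain on a cubic
    lattice with fluctuating bonds (lengths 2 to sqrt(10) lattice constants),
    residue-residue interactions from 20x20 knowledge-based contact matrices
    through a truncated generalized Lennard-Jones potential, and Metropolis
    Monte Carlo dynamics. Provides ensemble thermal sweeps of the radius of
    gyration, location of the characteristic temperature of non-monotonic
    response and its window, residue contact maps, spherically averaged
    structure factors, and effective-dimension estimates from their low-q
    power-law scaling. Includes synthetic generators (sequences, contact
    matrices, reference conformations) and an exact-enumeration Boltzmann
    oracle so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    seqinr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
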