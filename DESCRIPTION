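Package: brushpull
Title: Dissipative Particle Dynamics of Bottlebrush Polymers Pulled Across
    Supported Lipid Bilayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A coarse-grained dissipative particle dynamics (DPD) engine and
    analysis pipeline for studying how a bottlebrush polymer, dragged by a
    constant per-bead force, interacts with a substrate-supported phospholipid
    bilayer. Builds bead-spring topologies for lipids, bottlebrushes and
    solvent; integrates the equations of motion with the Groot-Warren modified
    velocity-Verlet scheme and a cell-list neighbor search; and computes the
    radius of gyration, the gyration-tensor shape factor, x-binned P2
    orientational order profiles, brush-membrane contact counts and landmark
    times of observable traces. Includes scaled-down presets, analytic test
    fixtures with known observables, and readers/writers for XYZ and
    LAMMPS-style trajectory and data files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
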