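Package: eprofiler
Title: Coarse-Grained Protein Energy Profiles and Their Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms three-dimensional protein structures into
    one-dimensional per-residue pseudoenergy profiles using an
    inverse-Boltzmann buriedness potential, and compares such profiles by
    dynamic-programming alignment with a permutation-calibrated distance
    score (dScore). Includes progressive multiple energy profile alignment
    (MEPAL) with UPGMA guide trees, consensus energies and per-column
    conservation, evaluation utilities (profile fragmentation, neural-gas
    clustering, normalized mutual information, Spearman rank correlation),
    and seeded synthetic-structure generators so the entire pipeline is
    testable without external structure sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
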