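Package: chimeraforge
Title: Automated Design and Structural Analysis of Single-Crossover Protein Chimeras
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing chimeric proteins by fragment recombination.
    Starting from a table of fragment-homology hits between protein domains,
    chimeraforge filters hits, builds fragment-similarity networks, maps
    alignments onto structures, superposes the shared fragment (globally or in
    gap-delimited segments), detects geometrically seamless fusion points, and
    assembles both single-crossover chimeras per fusion point, rejecting models
    with backbone clashes. A structural-analysis battery computes solvent
    accessible surface area, contact maps, relative contact order, salt
    bridges, hydrogen bonds and hydrophobic clusters. Includes a deterministic
    synthetic-structure generator for ideal-geometry helices and strands and
    engineered parent pairs with known fusion points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
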