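Package: coordenum
Title: Stereoisomer Enumeration and 3D Structure Generation for
    Mononuclear Coordination Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates the distinct stereoisomers of mononuclear octahedral
    and square-planar transition-metal complexes from SMILES-encoded ligands
    whose donor atoms are marked with atom-map numbers. Raw donor placements
    on the coordination polyhedron are deduplicated through sets of canonical
    molecular-graph signatures generated under the polyhedron's vertex
    rotation group (24 permutations for octahedra, 8 for square planes), with
    optional enantiomer merging via improper operations. Donor atoms that
    become tetrahedral stereocenters on coordination (e.g. secondary amines)
    are expanded into both configurations, and chemically infeasible
    arrangements (trans-chelating short bidentates, facially bound rigid
    tridentates) can be filtered out. Each surviving stereoisomer is embedded
    in three dimensions by bounds-matrix distance geometry with metal-center
    distance constraints, verified against the intended donor arrangement,
    and relaxed with a harmonic force field supplemented for dative bonds.
    Structures are written as XYZ files carrying a machine-readable record
    that allows lossless reload.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    tibble,
    yaml,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
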