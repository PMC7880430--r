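Package: agtpath
Title: Branched Metabolic Pathway Search by Atom Group Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds branched metabolic pathways between a source and a target
    compound in an atom-mapped reactant-pair network. Linear pathways are
    enumerated by shortest-path search and filtered to those that conserve
    atom groups (connected sets of covalently bonded atoms) from the source
    into the target, tracked through composed substrate-to-product atom
    mappings. Linear pathways are then merged at branched compounds under an
    overlapping or a non-overlapping rule, defined on the bond structure of
    the conserved atom groups, and ranked by a combined score of compound
    similarity, reaction Gibbs free energy and conserved atom groups.
    Includes the seven standard pathway-comparison metrics (largest common
    connected sub-graph ratio, compound and reaction sensitivity, positive
    predictive value and accuracy) and a seeded generator of synthetic
    atom-mapped networks with planted branched pathways for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    utils,
    stats
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
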