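Package: complexmodules
Title: Predicting Biological Modules in Protein Complexes from Chain
    Contact Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the quaternary structure of a protein complex as an
    undirected, labelled, weighted graph (the complex graph) whose vertices
    are protein chains and whose edge weights count residue-residue contacts
    under a sphere model for atoms (2.0 Angstrom radius for protein atoms,
    3.0 Angstrom for ligand atoms). Partitions the complex graph into
    structural modules with a from-scratch implementation of the Leiden
    community-detection algorithm optimizing resolution-parameterized
    weighted modularity, using a best-of-N independent-runs protocol.
    Includes mmCIF/PDB structure parsing, GML graph input/output, geometric
    centre layouts, adjusted Rand index evaluation against reference module
    assignments, inter-module interface statistics, and generators for
    synthetic multi-chain structures and planted-partition graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    data.table,
    stats,
    utils
Suggests:
    igraph,
    mclust,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
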