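Package: ccannotate
Title: Chemical Component Annotation for Macromolecular Structure Entries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies every small-molecule instance in a macromolecular
    structure entry, matches each against a chemical component dictionary by
    attribute-aware graph isomorphism, and scores near-matches with a
    five-category composite score (heavy atoms, chiral-center count,
    handedness, aromatic atoms, bond order). Bonds, hybridization, chirality
    parity and aromaticity are perceived directly from 3D coordinates.
    Covalent attachments to the surrounding structure are detected and capped
    with their leaving groups so absolute stereochemistry at attachment points
    is determinable, and peptide-like ligands can be decomposed ("chopped")
    into capped free-neutral subcomponents that are matched and ordered
    N-terminus to C-terminus. Includes a minimal PDBx/mmCIF chem_comp
    dictionary reader/writer, a PDB/mmCIF entry reader/writer, a deterministic
    synthetic fixture generator, and a batch-report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
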