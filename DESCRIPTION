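Package: ipscreen
Title: Interaction-Pattern Screening of Protein-Ligand Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects noncovalent protein-ligand interactions (hydrogen
    bonds, hydrophobic contacts, pi-stacking, halogen bonds) from 3D
    structures in PDB or mmCIF format, evaluates the ten brivudine (BVDU)
    interaction patterns A-J on each complex, and ranks ligands across a
    structure collection by the number of matched patterns for structure
    based drug repositioning. Includes scaffold-aware chemical similarity
    clustering, a drug-class by target-superfamily repositioning evidence
    matrix with coverage statistics, and a deterministic generator of
    synthetic binding-site fixtures realizing any implication-closed
    pattern subset.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    igraph,
    jsonlite,
    yaml,
    ChemmineR,
    stats,
    utils
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
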