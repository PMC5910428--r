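Package: profnet
Title: Residue-Profile Neural Networks for Fixed-Backbone Protein Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the per-position probability profile of the 20 amino
    acids from a protein backbone, for use in fixed-backbone computational
    protein design. Parses and filters PDB structures, extracts local
    structural environments (backbone dihedrals, backbone solvent accessible
    surface area, three-state secondary structure, backbone hydrogen bonds,
    and neighbor geometry expressed in a canonical residue frame), trains a
    shared-subnetwork neural architecture with class-weighted categorical
    cross entropy, evaluates predictions (overall and top-K accuracy,
    per-residue recall and precision, confusion probabilities, sequence
    identity, profile RMSE, contact-rank coverage), and exports top-K
    residue-type restraints as Rosetta resfiles. Includes an idealized
    backbone builder and synthetic dataset generator so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    Biostrings
Config/testthat/edition: 3
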