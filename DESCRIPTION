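Package: plyase
Title: Geometric Substrate-Specificity Analysis for Exolytic Alginate Lyases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for explaining polyM versus polyG substrate preference in
    PL15-family oligo-alginate lyases from active-site geometry. Builds
    enzyme-trisaccharide complexes by sequence-alignment-guided rigid
    superposition onto template complexes and ligand transplantation, perceives
    uronate sugar rings and binding subsites, places the C5 proton on the +1
    sugar geometrically, measures catalytic His/Tyr distances to that proton
    (per frame for multi-model trajectories), and classifies specificity with a
    distance-comparison rule. Includes a seeded generator of idealized
    synthetic complexes with ground-truth geometry for end-to-end validation,
    plus PDB/FASTA input-output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
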