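Package: mcdock
Title: Metal-Aware Docking of Metal-Organic Complexes to Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Docking of metal-organic complexes into rigid protein pockets
    with AutoDock-style atom typing extended by parametrized metal atom
    types. Metal-protein interactions are modelled with 12-10 (hydrogen-bond
    like, for NA/OA/SA acceptors) and 12-6 (HD, metal-assisted deprotonation)
    Lennard-Jones terms; an optional zero-parameter dummy atom marking the
    vacant coordination site supplies hydrogen-bond directionality. Pose
    search uses a genetic algorithm with Solis-Wets local refinement; metal
    well depths are fitted by Monte Carlo sampling against reference poses
    via a mean all-atom RMSD objective. Includes Tanimoto fingerprint and
    TM-score similarity utilities for train/test dataset curation, and
    deterministic toy-system generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
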