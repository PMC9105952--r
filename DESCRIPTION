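Package: poseprep
Title: Knowledge-Based Docking Restraints and Pose Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates knowledge-based restraints for protein-ligand docking
    and selects docked poses, following the strategy used in blind
    pose-prediction exercises such as the CELPP challenge. Given a query
    ligand and ligands retrieved from structurally similar binding pockets
    (aligned into a common frame), the package computes MACCS/Tanimoto and
    maximum-common-substructure (MCS) similarity, elucidates consensus
    pharmacophores with mandatory and optional feature spheres, chooses
    between tethered, pharmacophore-guided and free docking, prepares
    tethered ligand input and rDock-dialect cavity/restraint files, and
    evaluates docked poses with symmetry-corrected RMSD and per-method
    summary statistics. A synthetic fixture generator produces congeneric
    ligand series with planted scaffolds and feature points, and scored pose
    sets with known RMSD ground truth, for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR
Config/testthat/edition: 3
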