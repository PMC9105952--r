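# poseprep

Knowledge-based docking restraints and pose selection for blind
protein–ligand pose prediction.

## What it is for

Weekly blind challenges such as CELPP ask participants to predict, fully
automatically, how a query ligand binds dozens of protein targets.
Docking engines sample and score poses, but their accuracy improves
substantially when restrained with knowledge mined from structures
already in the PDB: ligands bound in the aligned pockets of close
homologues. `poseprep` implements that restraint-generation and
pose-selection core for computational chemists building such pipelines:

* **Ligand similarity** — MACCS 166-key/Tanimoto fingerprints and a
  size-aware maximum-common-substructure similarity,
  `TanimotoMCSS = NAB / (NA + NB − NAB)`, where `NA`, `NB` are the
  heavy-atom counts of the two molecules and `NAB` that of their MCS;
* **Reference-ligand selection and cavity ranking** — the retrieved
  ligand maximizing MACCS Tanimoto + TanimotoMCSS defines each candidate
  cavity; cavities are ranked by the MCS score;
* **Consensus pharmacophores** — feature perception (AROM, HDON, HACC,
  LIPO, POSC, NEGC) on aligned 3D ligands, diversity clustering at MACCS
  Tanimoto 0.9, and support-bracket classification: features shared by
  more than 45% of representatives become mandatory restraints, 20–44%
  optional ("at least one" semantics);
* **Strategy selection** — tethered docking when the best TanimotoMCSS
  is strictly above 0.5, pharmacophore-guided when more than 5 diverse
  ligands are available, free docking otherwise;
* **Tether preparation** — Kabsch superposition of the query conformer's
  MCS atoms onto the reference ligand and the `TETHERED ATOMS` SDF
  annotation consumed by rDock;
* **rDock-dialect files** — pharmacophore restraint spheres
  (`x y z radius TYPE`) and reference-ligand cavity definition files;
* **Pose selection and evaluation** — `SCORE.INTER`-sorted pose
  selection, cavity-rank-dominated submission choice, symmetry-corrected
  RMSD (minimum over graph automorphisms, no re-superposition) and
  per-method summary tables with the strict sub-2 Å success criterion;
* **Synthetic fixtures** — seeded, byte-stable generators for congeneric
  aligned series with planted scaffolds/features and scored pose sets
  with planted RMSD ground truth.

Chemical I/O is MDL V2000 SDF/MOL with verbatim SD-field handling, plus
SMILES input (parsed through Open Babel via ChemmineOB). The docking
engine itself, protein preparation, and database retrieval are out of
scope; receptor files are passed through untouched.

## A worked example

```r
library(poseprep)

q    <- read_smiles("Cc1ccccc1Cl query")[[1]]
refs <- read_smiles("c1ccccc1C toluene\nc1ccccc1Cl chlorobenzene\nCCCCCC hexane")
similarity_table(q, refs)
#>   query_id        ref_id tanimoto_maccs tanimoto_mcss combined n_a n_b n_ab
#> 1    query       toluene         0.4000        0.8750     1.27   8   7    7
#> 2    query chlorobenzene         0.7000        0.8750     1.57   8   7    7
#> 3    query        hexane         0.0526        0.0769     0.13   8   6    1
select_reference_ligand(similarity_table(q, refs))
#> [1] "chlorobenzene"
```

Toluene and chlorobenzene both contain a 7-atom common substructure with
the query (`TanimotoMCSS = 7/8 = 0.875`); the MACCS score breaks the tie
in favour of chlorobenzene. Since 0.875 > 0.5, this cavity would be
docked tethered.

End to end on a synthetic two-cavity target:

```r
sc  <- gen_cavity_scenario(seed = 11, n_cavities = 2, which_correct = 1,
                           n_ligands = 3)
rep <- run_target(target_bundle("demo", sc$query, unname(sc$cavities)),
                  out_dir = tempdir())
rep$ranked_cavities
#> [1] "cavity_1" "cavity_2"
rep$cavities$cavity_1$decision$protocol
#> [1] "TETHERED"

q3    <- embed_molecule(sc$query)
poses <- gen_pose_set(q3, pose_spec(seed = 5, target_rmsds = c(0.8, 1.5, 3.2)))
sel   <- select_submission(list(cavity_1 = poses, cavity_2 = list()),
                           rep$ranked_cavities)
symmetry_rmsd(sel$mol, q3)
#> [1] 0.8000025
```

The cavity holding the scaffold-sharing series ranks first, tethered
docking is chosen (best TanimotoMCSS 0.875), and the submitted pose is
the planted best one (0.8 Å, strictly below the 2 Å success threshold).

See `vignettes/restraint-generation.Rmd` for the full model description,
parameter defaults and design rationale.

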