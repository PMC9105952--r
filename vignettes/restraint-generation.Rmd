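---
title: "Knowledge-based restraint generation and pose selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-based restraint generation and pose selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(poseprep)
```

## The problem

Blind pose-prediction exercises such as the CELPP challenge deliver, every
week, a query ligand and candidate receptor structures for dozens of
protein targets. Docking engines alone frequently mis-rank poses, but the
Protein Data Bank usually already holds structures of close homologues
with ligands bound in the same pocket. `poseprep` implements the
knowledge-based core of such a pipeline: it mines ligands retrieved from
aligned pockets of similar proteins, quantifies their similarity to the
query, and converts what it finds into docking restraints — a tethered
substructure when one retrieved ligand is very similar, a consensus
pharmacophore when many diverse ligands are available, or nothing (free
docking) when neither condition holds. It also selects the submission
pose from scored docking output and evaluates predictions with
symmetry-corrected RMSD.

The package does **not** run a docking engine, prepare proteins, or query
structure databases. It consumes aligned ligands (as a pocket-alignment
tool would deliver them) and scored pose sets, and emits the artifacts a
docking engine consumes: tethered SDF, pharmacophore restraint files and
reference-ligand cavity definitions in the rDock dialect.

## Similarity model

Two complementary similarity measures are computed between the query
ligand and every retrieved ligand:

* **MACCS/Tanimoto** — the published 166 structural keys (computed through
  Open Babel) compared with the Tanimoto coefficient
  $T(A,B) = |A \cap B| / |A \cup B|$.
* **MCS Tanimoto** — a size-aware similarity built on the maximum common
  substructure:
  $$\mathrm{Tanimoto}_{MCSS} = \frac{N_{AB}}{N_A + N_B - N_{AB}}$$
  where $N_A$, $N_B$ are heavy-atom counts of the two molecules and
  $N_{AB}$ the heavy-atom count of their MCS. It is 1 exactly for
  identical molecules.

The **reference ligand** for a cavity is the retrieved ligand maximizing
the *sum* of the two scores: a similar ligand of similar size, which also
keeps the reference-ligand cavity definition adapted to the query.
Cavities are ranked by their reference ligand's MCS Tanimoto score.

### MCS conventions

The MCS operation must be pinned down beyond the formula; the choices
here follow common `FindMCS` practice:

* atoms match by element; ring atoms only match ring atoms (preventing
  chains threading through rings, which would produce absurd tethers);
* bonds match by order, with aromatic treated as its own order;
* only **connected** common substructures count;
* the branch-and-bound search is canonical (each mapping visited once),
  so results are deterministic; when several maximum mappings exist the
  first in enumeration order is kept and the multiplicity recorded;
* a per-pair wall-clock cap (default 60 s, generous for drug-sized
  molecules) returns the best mapping found so far, flagged partial.

All similarity, MCS and RMSD computations are heavy-atom-only; hydrogen
counts, where chemistry needs them (donor perception), are recovered from
standard valences and formal charges.

## Consensus pharmacophore

Feature points are perceived per aligned ligand with an explicit rule
table (an approximation of the Align-it definitions, normative for this
package): `AROM` at aromatic-ring centroids, `HDON` at N/O bearing
hydrogen, `HACC` at N/O with a free lone pair, `LIPO` at centroids of
connected groups of two or more apolar carbons, `POSC`/`NEGC` at formally
charged atoms. Hybrid and exclusion-volume feature types are outside the
vocabulary.

Two protocol versions are provided:

* **Version 1** groups features across ligands (same type, centers within
  a tolerance), ranks groups by the number of ligands in which they
  appear, and takes the two highest as mandatory restraints.
* **Version 2** first clusters ligands by MACCS Tanimoto at 0.9
  (single linkage; the cluster centroid — the member with maximal mean
  similarity to its cluster — represents it), removing redundancy. Groups
  supported by **more than 45%** of the representatives become mandatory
  restraints; groups with support **between 20% and 44%** (closed
  interval) become optional restraints, of which the docking engine must
  satisfy at least one (`PH4_NOPT = 1`).

Numerical choices the protocol description leaves open, fixed here:

* spatial grouping tolerance 1.5 Å (configurable `ph4_tol`): larger than
  typical pocket-alignment jitter, smaller than the distance between
  adjacent substituent positions on a six-ring;
* restraint sphere radius 1.0 Å (configurable `ph4_radius`);
* the two support brackets do not tile $(0.44, 0.45]$; supports falling
  in the gap are dropped with a message rather than silently bridged;
* grouping is greedy from the most-populated neighbourhood, over points
  in a canonical sort order, so the result is invariant to ligand input
  order;
* version 1 never states a spatial tolerance; it reuses `ph4_tol`.

## Strategy selection

The decision cascade, with strict inequalities exactly as the protocol
states them:

1. **TETHERED** if the reference ligand's MCS Tanimoto is $> 0.5$;
2. else **PH4** if the number of *diverse* ligands (cluster
   representatives, not raw ligand count — clustering exists precisely to
   de-duplicate) is $> 5$;
3. else **FREE**.

Equality at either boundary falls through. The earlier development-phase
tether cutoff of 0.65 is retained as the `"legacy"` preset (default off);
0.5 is the validated default. Each cavity is decided independently, and
every decision is recorded with its thresholds in a JSON report.

Tether preparation superposes the query conformer's MCS atoms onto the
reference ligand's matched atoms with a least-squares proper rotation
(Kabsch, SVD with determinant correction) and applies that single rigid
transform to the whole conformer — non-MCS atoms are *not* re-minimized.
The `TETHERED ATOMS` SD field lists the 1-based query atom indices of the
MCS, ascending, the dialect rDock's tethered mode consumes. Tethering
requires at least 3 mapped atoms; fewer is an error advising fallback.
Internally all atom indices are 1-based (the R convention, matching the
V2000 and tether dialects).

## Pose selection and evaluation

Docked poses carry an intermolecular score (`SCORE.INTER`; lower is
better, an energy-like convention). Within a cavity the best pose is the
score minimum with earliest-wins ties. Across cavities, **cavity rank
dominates**: the submission is the best pose of the highest-MCS-ranked
cavity that produced any pose, regardless of scores elsewhere — scores
from different cavity contexts are not comparable. The full ranking is
exposed so a caller can revisit this policy.

Symmetry-corrected RMSD minimizes the heavy-atom RMSD over the graph
automorphisms of the reference (element, ring and bond-label preserving),
so topologically equivalent atoms — benzene carbons, for example — are
matched optimally. There is **no re-superposition**: docked and reference
poses share the receptor frame. Automorphism enumeration is capped at
10,000; beyond the cap the identity order is used with a warning. A
prediction is a success when its RMSD is strictly below 2 Å (a flag
switches to inclusive comparison, since tabulated conventions vary).
Summaries report n, mean, standard deviation (0 for a single value), min,
max and quartiles by linear interpolation between closest ranks (R's
default type 7, stated because tabulated protocols rarely define it).

## What the synthetic generators emulate

`gen_series()` emulates a congeneric series retrieved from aligned
pockets: every ligand shares a scaffold embedded at fixed template
coordinates in a common frame, decorated from a substituent pool, with
feature groups planted in a controlled fraction of ligands
(carrier count = `round(fraction * n)`), plus Gaussian coordinate jitter
(default 0.05 Å) emulating alignment error. The 3D embedding is a
deterministic planar template — idealized bond lengths, regular-polygon
rings — not a conformer generator, so outputs are platform-independent
and byte-stable. `gen_pose_set()` plants poses at requested
symmetry-corrected RMSDs from a reference (rigid perturbations
root-solved to within $10^{-3}$ Å) with scores following
$-25 + 3 \cdot \mathrm{RMSD}$ plus seeded noise; only monotonicity is
contractual. `gen_cavity_scenario()` builds multi-cavity targets where
the correct cavity holds scaffold-sharing analogs and decoys hold
dissimilar acyclic ligands.

What these fixtures do **not** capture: force-field-quality geometry,
conformational flexibility, receptor structure, scoring-function noise
structure, and the failure modes of real pocket retrieval (wrong or
missed cavities, dimer interfaces, cofactors). Tests passing on them
certify the algorithmic contracts — similarity arithmetic, consensus
bracket logic, cascade boundaries, rigid-transform exactness, RMSD
symmetry correction — not prospective docking accuracy.

## A worked example

```{r example}
set.seed(0)
sc <- gen_cavity_scenario(seed = 11, n_cavities = 2, which_correct = 1,
                          n_ligands = 3)
out <- file.path(tempdir(), "demo")
rep <- run_target(target_bundle("demo", sc$query, unname(sc$cavities)),
                  out_dir = out)
rep$ranked_cavities
rep$cavities$cavity_1$decision$protocol

q3 <- embed_molecule(sc$query)
poses <- gen_pose_set(q3, pose_spec(seed = 5, target_rmsds = c(0.8, 1.5, 3.2)))
sel <- select_submission(list(cavity_1 = poses, cavity_2 = list()),
                         rep$ranked_cavities)
symmetry_rmsd(sel$mol, q3)
```

## Problem sizes and limitations

The shipped tests and the acceptance script run on series of up to 10
ligands of roughly 6–15 heavy atoms, pose sets of 4–6 poses, and
corpora of 50 random molecules of up to 8 heavy atoms for oracle
comparisons — sizes at which the exhaustive test oracles stay exact and
the whole suite completes in about a minute.

Known limitations:

* the MCS is connected-only; disconnected common substructures are out
  of scope;
* the template embedder supports single and pendant rings, not fused
  systems — adequate for fixtures, not a conformer generator;
* aromatic perception is a Hückel-style rule for 5- and 6-rings, not a
  full model;
* the Daylight-fingerprint similarity used by challenge organisers for
  the hiTanimoto category is noted but not implemented;
* receptor files are opaque pass-through; MOL2/PDB contents are never
  parsed.
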