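---
title: "Docking-informed kinase affinity prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Docking-informed kinase affinity prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kindock)
```

## The problem

Physics-based docking places kinase inhibitors into binding sites well, but
the engines' own scoring functions correlate poorly with measured binding
affinity. kindock implements the alternative this package is built around:
treat the docked pose as a *feature source* rather than trusting the engine
score. A protein–ligand interaction fingerprint of each pose is fed to a
neural network trained on literature pChEMBL values (pooled pIC50/pKi/pKd,
so higher = more potent), and the per-pose predictions are averaged into a
single affinity estimate per compound–kinase pair.

The package covers the whole workflow at desk scale: curation of activity
and structure tables, pose management with a steric-clash filter, ECFP and
PLEC fingerprints, the scoring network with leakage-aware splits, flat-mean
aggregation, an SQLite pose database, and a synthetic-fixture module that
makes all of it testable without any external download.

## Curation model

**Compounds.** Drug-likeness bounds are deliberately lax so the set still
resembles real medicinal chemistry: molecular weight 250–750 Da, H-bond
donors ≤ 10, acceptors ≤ 15, rotatable bonds ≤ 15. All bounds are
inclusive; where the underlying sources state "MW ≤ 750" and "between 250
and 750" side by side, the lower bound of 250 Da is adopted. Descriptors
follow the chemistry toolkit's default definitions (OpenBabel MW/HBD/HBA;
rotatable bonds as single acyclic bonds between non-terminal heavy atoms
excluding triple-bond neighbours), and the definitions are recorded in the
dataset metadata. A compound with a missing descriptor is neither passed
nor failed but flagged undetermined (`NA`) — silently failing it would make
filter monotonicity unauditable.

**Activities.** Mutant-protein measurements are discarded; the remaining
records are grouped by (compound, kinase) and averaged with a plain
arithmetic mean, pooling pIC50/pKi/pKd indiscriminately. No
activity-type weighting is attempted because no defensible weights exist
without the original assay metadata.

**Structures.** Gates on resolution (≤ 2.5 Å), a KLIFS-style quality score
(≥ 8) and missing residues (≤ 5) are applied jointly (their order cannot
matter for a conjunction). Per kinase and per conformational state
(DFG-in/out × αC-helix-in/out, with "out-like" DFG annotations folded into
"out" to keep the four-state grid) the highest-quality structure is
retained, so a kinase contributes at most four structures. Quality ties
break by lower resolution, then lexicographic structure id — determinism
is worth more than any tie-break cleverness here.

## Clash score

Docked poses, particularly from generative pose samplers, can be
physically impossible. The filter used here scores a pose by summed van
der Waals overlap: protein atoms within 4.0 Å of any ligand atom are
selected (closed boundary), and every (ligand atom, selected protein atom)
pair contributes

$$c(d) = \max(0,\; r_1 + r_2 - d),$$

with $d$ the pair distance and $r_1, r_2$ Bondi vdW radii (H 1.20, C 1.70,
N 1.55, O 1.52, S 1.80, F 1.47, Cl 1.75, Br 1.85, I 1.98 Å; unknown
elements fall back to 1.50 Å with a warning). The linear overlap form is
the simplest function consistent with the roles of $d$, $r_1$ and $r_2$;
since contributions vanish beyond $r_1 + r_2 < 4$ Å, the 4 Å selection is
exactly equivalent to the all-pairs sum, which the tests exploit as a
brute-force oracle. All atoms present in the input files are used as
given; no hydrogens are added or removed, because docked outputs differ in
protonation conventions and silent editing would make scores incomparable.

The acceptance threshold is data-driven: `fitClashThreshold()` fits a
normal distribution (sample mean and SD) to a sample of clash scores and
returns the 3σ upper limit μ + 3σ. The package default threshold is 10.0,
the operating criterion "clash < 10" (strict inequality) under which
roughly 99.7% of a single well-behaved population is retained; the fit
function is exported so the threshold can be recalibrated for a new engine.

## Fingerprints

Both fingerprints build on iterative neighborhood hashing. Every atom
carries the ECFP-standard invariant tuple (element, formal charge,
aromatic flag, heavy-atom degree, attached-hydrogen count, ring
membership). The depth-0 identifier hashes this tuple; the depth-k
identifier hashes the depth-(k−1) identifier together with the *sorted*
list of (bond order, neighbour depth-(k−1) identifier) pairs, which makes
identifiers invariant under atom relabeling by construction. The hash is a
fixed 32-bit FNV-1a over the serialised tuple — chosen so fingerprints are
bit-identical across platforms and sessions with no external dependency.

* **ECFP**: all identifiers of depth 0..radius (default 2, the ECFP4
  configuration) set bit `id mod nbits` in a 2048-bit vector.
* **PLEC**: heavy-atom contacts between ligand and protein within 4.5 Å
  (closed boundary) are enumerated; for each contact, every depth
  combination (i ≤ 2 ligand-side, j ≤ 4 protein-side — the original PLEC
  defaults, exposed as parameters) hashes the identifier pair into a
  65536-bit vector. The full Cartesian product of depths is used; PLEC
  implementations differ on this point, so it is stated explicitly.
  Protein-side environments are computed on the residue-local graph
  actually supplied (bonds inferred within residues from covalent radii),
  so fingerprints never depend on atoms absent from the input.

Widths must be powers of two, keeping `mod` a clean bit-mask of the hash.

## Scoring network

A 3-layer fully connected network maps the fingerprint to pChEMBL:
input → 4000 → 1000 → 1, rectified linear units after the first two
layers, linear output, dropout 0.25 on the input and both hidden
activations during training (inverted scaling, so inference needs no
correction). The output layer is left linear: clamping a regression output
at zero serves no purpose when labels live around 2–12. Training minimises
mean squared error with Adam at a fixed learning rate of 1e-5, batch size
128, for a fixed 100 epochs; after every epoch the held-out R² is recorded
and the *best checkpoint*, not the final epoch, is the returned model. R²
is the squared Pearson correlation (the scoring-function convention; the
coefficient-of-determination variant is available behind a flag), and the
checkpoint metric is the same R² used for final reporting so the two can
never disagree. Weights initialise with the standard uniform fan-in scheme
from the configuration seed; the optimiser choice (Adam) is the package's
own, made for robustness at a fixed learning rate. Non-finite losses abort
with a diagnostic rather than silently continuing.

## Leakage-aware splits

Three 80:20 strategies: by record (`random`), by compound (test compounds
completely unseen) and by kinase (test kinases completely unseen). Splits
are additionally curated for distributional similarity: 25 seeded
candidate partitions are drawn and the one with the smallest
Kolmogorov–Smirnov statistic between train and test pChEMBL distributions
is returned — a deterministic, seed-reproducible reading of "splits were
curated so the test distribution is similar". Entity splits add whole
entities to the test side only while doing so moves the record count
toward the 20% target, so with balanced fixtures the achieved sizes are
exact.

## Aggregation

For one compound–kinase pair, the engine's top 3 poses (by engine rank —
the built-in ranking is decent at prioritising poses even when its score
is not predictive) of every structure and every stereoisomer are scored,
and the estimate is the *flat* arithmetic mean over all retained scores.
Mean-of-group-means is available behind a flag, but the flat mean over
"all options" is the default; on enumerated cases the two differ
(`[6,6,6]` and `[9,9]` give 7.2 flat vs 7.5 hierarchical).
`evaluateAggregationStrategies()` compares top-1/top-2/top-3/all-mean on
the same predictions; with independent per-pose noise, top-3 averaging
beats the top pose by simple variance reduction, which the acceptance
suite verifies by simulation.

## Pose database and pipeline

An SQLite file holds six tables — proteins, structures, compounds,
isomers, activities, poses — with enforced foreign keys and a uniqueness
constraint on (isomer, structure, engine, rank). Pose mol-blocks are
zlib-compressed blobs with the uncompressed size stored alongside.

Docking runs behind a small engine contract (`dockIsomer()`): an engine
declares whether it needs a search box and returns ranked poses,
deterministically for a given seed where it can. The bundled mock engine
fabricates a rigid conformer directly from the molecular graph (a spectral
layout of the graph Laplacian scaled to bond-length scale, with a seeded
symmetry-breaking jitter and sign-fixed eigenvectors) and places seeded
rigid copies inside the box. This construction is exactly reproducible,
which the end-to-end determinism guarantee relies on; the toolkit 3D
builder exposed as `embedMolecule()` is stochastic between calls and is
therefore kept out of the mock path. Docking boxes are built from pocket
points as the padded (default 5 Å per face) axis-aligned bounding box;
cavity detection itself is out of scope and pocket points are supplied by
the caller or the fixtures.

`runPipeline()` chains enumeration → docking → clash filter (default
threshold 10.0) → PLEC → scoring → aggregation, persisting every pose.
Scoring always proceeds from the *persisted* pose representation
(mol-block text at 4-decimal precision): fresh runs store then re-read
their poses, so a fresh run and a database re-run traverse one identical
code path and produce byte-identical CSVs. Per-compound failures are
recorded, not fatal: unparsable SMILES yield `invalid_smiles` records,
pairs whose every pose fails the clash filter `no_valid_pose`, and input
compounds are conserved as records one-for-one. Stereoisomer enumeration
caps at 32 isomers per compound (a combinatorial guard; the pipeline
defaults to 8) with a warning on truncation; an isomer that fails
preparation skips only that isomer.

## Stereoisomer enumeration

Unassigned tetrahedral centres and unassigned acyclic C=C geometries are
enumerated by inserting stereo marks into the canonical SMILES and
re-canonicalising each assignment with OpenBabel. The canonicaliser drops
marks on non-stereogenic atoms, so false candidates collapse during
deduplication and only genuine stereoisomers survive — meso forms and
pseudo-centres are handled without any explicit CIP machinery. Already
specified stereochemistry is preserved untouched.

## Synthetic fixtures: what they emulate and what they do not

The `synthetic` generators are first-class, tested code and define the
package's study conditions:

* `makeToyComplex()` — protein atoms on a jittered shell (radius = ligand
  extent + 8 Å) with a chain-graph ligand displaced to hit a target clash
  score within ±10% (grid scan plus refinement); target 0 gives strictly
  clash-free geometry.
* `plantSar()` — sparse Bernoulli fingerprints (density 0.05), fixed
  weights ~ Normal(0, 0.3), labels with Normal(0, 0.3) noise. The analytic
  noise ceiling v/(v + σ²) gives the recovery tests an exact target.
* `makeToyBenchmark()` — raw curation tables with *planted* defect
  fractions (10% low-MW compounds, 10% mutant records, 25% poor-resolution
  structures), so curation tests assert exact survival counts rather than
  statistical tendencies.

All generators are pure functions of their seed, using R's
platform-independent RNG with state save/restore so package calls never
perturb user-level randomness. The fixtures exercise the real parsers
(CSV/PDB/SDF dialects), but they do **not** mimic real kinase pocket
geometry, real chemistry of binding, or real affinity distributions:
passing tests demonstrate that the machinery is correct and
deterministic, not that toy-scale models transfer to experimental data.
The published-scale results (hundreds of kinases, ~2×10⁵ activities,
GPU docking) are out of reach of a desk-scale build by design.

## Problem sizes and numerical choices

The test and acceptance workloads are sized for a single CPU: 200 random
complexes for the clash oracle, 10⁴ draws for threshold calibration, the
SAR recovery experiment at n = 5000 training / 1250 held-out samples with
a 256-bit toy width and 512/128 hidden units (the published 4000/1000
architecture at the published widths is configuration, not code, and
trains identically), learning rate 5e-4 scaled so Adam converges within
the fixed 100-epoch schedule, and a 10-compound × 3-kinase toy pipeline.
Other choices worth stating: closed boundaries everywhere a cutoff
appears (4.0 Å selection, 4.5 Å contacts, inclusive rule bounds);
eigenvector signs in the spectral conformer fixed by first-nonzero
convention; clash and distance computations guard the tiny negative
round-off under `sqrt`; empty inputs error early and explicitly rather
than propagating empty frames.

## Known limitations

* Real docking engines are wrapped by contract only; no external engine
  ships with the package, and absent engines must fail loudly, never fall
  back to the mock silently.
* OpenBabel's 3D builder is stochastic; reproducibility of real-engine
  preparations therefore comes from persisting conformers in the
  database, not from the builder.
* The per-atom aromatic and hydrogen annotations derive from the
  canonical SMILES and standard valence rules; exotic valences and
  organometallics are outside the supported chemistry.
* Clash pairs are ligand-to-protein only, with atom-centre selection;
  intra-protein strain is invisible to the filter.
* The hierarchical (mean-of-means) aggregation and the
  coefficient-of-determination R² exist behind flags but are not the
  defaults anywhere.
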