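# kindock

Docking-informed, kinome-wide binding affinity prediction in R.

Docking engines place kinase inhibitors into binding sites far better than
their built-in scoring functions predict affinity. `kindock` implements the
workflow that exploits this: docked poses are treated as a *feature source*
— each pose is encoded as a protein–ligand extended connectivity (PLEC)
bit fingerprint and scored by a neural network trained on literature
pChEMBL values (pooled pIC50/pKi/pKd, higher = more potent), and the
per-pose predictions are averaged into one affinity estimate per
compound–kinase pair. The package is aimed at computational chemists who
want a self-contained, reproducible implementation of this pipeline at
desk scale: every stage is exercised end to end with deterministic
synthetic fixtures and a mock docking engine, with external engines
pluggable behind a small contract.

## What is in the package

* **Curation** — drug-likeness filtering of compounds (MW 250–750 Da,
  HBD ≤ 10, HBA ≤ 15, RotB ≤ 15, all inclusive), mutant removal and
  per-pair arithmetic averaging of activities, and structure selection
  (resolution ≤ 2.5 Å, quality ≥ 8, missing residues ≤ 5; best structure
  per DFG × αC-helix state, at most 4 per kinase): `buildDataset()`.
* **Clash filtering** — a pose steric score summing the linear van der
  Waals overlap `max(0, r1 + r2 − d)` over ligand–protein atom pairs
  within 4 Å of the ligand, with a data-driven acceptance threshold
  `μ + 3σ` fitted to a score sample (package default 10.0, criterion
  `clash < 10`): `poseClashScore()`, `fitClashThreshold()`,
  `filterPoses()`.
* **Fingerprints** — deterministic ECFP (2048 bits, radius 2) and PLEC
  (65536 bits, ligand depth 2, protein depth 4, 4.5 Å contacts) built on
  FNV-1a-hashed iterative neighborhood identifiers: `ecfp()`, `plec()`.
* **Scoring network** — a 3-layer fully connected network
  (input → 4000 → 1000 → 1, ReLU, dropout 0.25, Adam at lr 1e-5, batch
  128, 100 epochs, best checkpoint returned) with leakage-aware
  random/compound/kinase 80:20 splits curated by Kolmogorov–Smirnov
  distance: `trainScoringNetwork()`, `makeSplits()`, plus per-kinase ECFP
  models for kinases with ≥ 100 inhibitors: `trainPerKinase()`.
* **Pipeline and pose database** — SQLite persistence of proteins,
  structures, compounds, isomers, activities and zlib-compressed poses
  with enforced foreign keys; stereoisomer enumeration; flat-mean
  aggregation of the top-3 poses per structure and isomer:
  `runPipeline()`, `dockDatabase()`, `trainFromDatabase()`,
  `aggregatePrediction()`.
* **Synthetic fixtures** — seeded generators for toy complexes with
  controlled clash, planted linear structure–activity data with an
  analytic noise ceiling, and raw curation tables with planted filter
  violations: `makeToyComplex()`, `plantSar()`, `makeToyBenchmark()`.

A thin command-line front end (`inst/exec/kindock`) exposes the
`curate` / `dock` / `fingerprint` / `train` / `predict` /
`filter-poses` / `db-audit` workflow over files.

## Worked example

```r
library(kindock)

# 1. synthetic raw tables with planted curation defects
tables  <- makeToyBenchmark(seed = 42, nKinases = 3, nStructuresPerKinase = 2,
                            nCompounds = 30, activitiesPerCompound = 2)
dataset <- buildDataset(tables$activities, tables$compounds, tables$structures)
dataset
#> CuratedDataset: 27 compounds, 36 activities, 4 structures (2 kinases)

# 2. persist, dock with the mock engine, train a toy scoring network
db <- dbInit(tempfile(fileext = ".sqlite"))
dbStoreDataset(db, dataset)
dockDatabase(db, mockEngine(), nPoses = 5, seed = 42)
fit <- trainFromDatabase(db, strategy = "compound",
                         spec = scoringNetworkSpec(4096, 64, 16),
                         config = trainingConfig(learningRate = 1e-3,
                                                 epochs = 10, batchSize = 32,
                                                 seed = 42))
fit$model
#> ScoringNetwork: 4096 -> 64 -> 16 -> 1 (dropout 0.25)
#>   best checkpoint: epoch 9, test metric 0.0120

# 3. predict a new compound against two kinases
records <- runPipeline("CC(F)c1ccccc1",
                       unique(structures(dataset)$accession)[1:2],
                       mockEngine(), db, fit$model, seed = 42)
for (r in records) show(r)
#> PredictionRecord CC(c1ccccc1)F x KIN002 [mock]: predicted pChEMBL 3.562 from 12 poses
#> PredictionRecord CC(c1ccccc1)F x KIN003 [mock]: predicted pChEMBL 2.896 from 12 poses
```

Three compounds were dropped by the planted molecular-weight violations,
mutant records were removed before averaging, and one kinase lost all of
its structures to the resolution gate. The 12 poses per record are the
top 3 clash-accepted poses of each of 2 structures × 2 enantiomers (the
query compound has one unassigned stereocentre). The near-zero test
metric of the toy network is expected: mock-engine poses and random toy
affinities carry no learnable signal — the package's learning capacity is
demonstrated instead by the planted-SAR recovery experiment, where the
network reaches the analytic noise ceiling (see the acceptance script).

## Scope

Real docking engines (Vina-family, diffusion-based samplers), cavity
detection, and the published large-scale dataset are out of scope; the
engine contract, the box builder, and the fixtures stand in for them at
desk scale. See the methods vignette (`vignettes/kindock-methods.Rmd`)
for the models, parameter choices, and known limitations.
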