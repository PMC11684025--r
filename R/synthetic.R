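# Deterministic synthetic fixtures: toy complexes with controlled clash,
# planted structure-activity data, and raw curation tables with planted
# filter violations. Every generator is a pure function of its arguments
# (seed included); fixtures are written in the same CSV/PDB/SDF dialects
# the real pipeline reads.

#' Toy ligand library
#'
#' A small fixed set of chemically valid molecules (5-15 heavy atoms), some
#' with unassigned stereocentres or double-bond geometries, used by the
#' synthetic benchmark so that isomer-enumeration and fingerprint code
#' paths are exercised with guaranteed-parsable input.
#'
#' @return character vector of SMILES.
#' @export
toyLigandLibrary <- function() {
  c("CCOC(=O)CC",            # ester
    "CC(F)c1ccccc1",         # benzylic stereocentre
    "CC=CC(N)=O",            # unassigned enamide geometry
    "CCC(O)CC",              # pentanol
    "Clc1ccc(CN)cc1",        # para-substituted ring
    "CC(C)Cc1ccc(O)cc1",     # phenol
    "NC(=O)CCF",             # fluoroamide
    "CN1CCCC1",              # pyrrolidine
    "OCC(O)C(O)CO",          # polyol with stereocentres
    "CSc1ccncc1")            # thioether pyridine
}

# compact deterministic ligand cluster built by a self-avoiding random walk
.toyLigandCoords <- function(nAtoms) {
  X <- matrix(0, nAtoms, 3)
  for (k in seq_len(nAtoms)[-1]) {
    repeat {
      step <- stats::rnorm(3)
      step <- 1.5 * step / sqrt(sum(step^2))
      cand <- X[k - 1L, ] + step
      if (k == 2L || min(sqrt(rowSums(sweep(X[1:(k - 1L), , drop = FALSE],
                                            2, cand)^2))) > 1.2) break
    }
    X[k, ] <- cand
  }
  sweep(X, 2, colMeans(X))
}

#' Generate a toy protein-ligand complex with controlled clash
#'
#' Places protein atoms on a jittered spherical shell and a chain-graph
#' ligand displaced from the shell centre so that its clash score is within
#' 10 percent of `targetClash` (grid scan plus local refinement of the
#' displacement); `targetClash = 0` yields a strictly clash-free complex.
#' Fully deterministic given `seed`.
#'
#' @param seed integer seed.
#' @param nProteinAtoms,nLigandAtoms atom counts (>= 1).
#' @param targetClash desired clash score (Angstrom, >= 0).
#' @return list with elements `protein` ([ProteinStructure-class]) and
#'   `pose` ([LigandPose-class]).
#' @export
makeToyComplex <- function(seed = 1L, nProteinAtoms = 60L, nLigandAtoms = 8L,
                           targetClash = 0) {
  stopifnot(nProteinAtoms >= 1L, nLigandAtoms >= 1L, targetClash >= 0)
  .withSeed(seed, {
    lig <- .toyLigandCoords(nLigandAtoms)
    ligExtent <- max(sqrt(rowSums(lig^2)))
    R <- ligExtent + 8
    # jittered shell
    dirs <- matrix(stats::rnorm(3 * nProteinAtoms), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    radii <- R + stats::runif(nProteinAtoms, -0.5, 0.5)
    P <- dirs * radii
    protEl <- rep(c("C", "N", "O", "S"), length.out = nProteinAtoms)
    ligEl <- rep(c("C", "C", "N", "O"), length.out = nLigandAtoms)
    protein <- new("ProteinStructure", structureId = sprintf("toy-%d", seed),
                   atoms = data.frame(element = protEl, x = P[, 1], y = P[, 2],
                                      z = P[, 3],
                                      resno = as.integer(ceiling(seq_len(nProteinAtoms) / 4)),
                                      resname = "TOY", stringsAsFactors = FALSE))
    mkPose <- function(X) {
      g <- new("MolGraph",
               atoms = data.frame(element = ligEl, charge = 0L,
                                  aromatic = FALSE, nH = 0L,
                                  stringsAsFactors = FALSE),
               bonds = if (nLigandAtoms > 1L)
                 data.frame(i = seq_len(nLigandAtoms - 1L),
                            j = seq_len(nLigandAtoms - 1L) + 1L, order = 1L)
               else data.frame(i = integer(), j = integer(), order = integer()))
      new("LigandPose", poseId = sprintf("toy-pose-%d", seed),
          isomerId = "toy-isomer", structureId = protein@structureId,
          engine = "mock", rank = 1L, engineScore = 0, clashScore = NA_real_,
          graph = g, coords = X)
    }
    if (targetClash == 0) {
      pose <- mkPose(lig)
      pose@clashScore <- poseClashScore(pose, protein)$total
      return(list(protein = protein, pose = pose))
    }
    clashAt <- function(t) {
      poseClashScore(mkPose(sweep(lig, 2, c(t, 0, 0), "+")), protein,
                     selectionCutoff = Inf)$total
    }
    ts <- seq(0, R + ligExtent + 4, by = 0.05)
    cl <- vapply(ts, clashAt, numeric(1))
    kBest <- which.min(abs(cl - targetClash))
    # local refinement around the best grid point
    tLo <- max(0, ts[kBest] - 0.05); tHi <- ts[kBest] + 0.05
    fine <- seq(tLo, tHi, length.out = 41)
    clF <- vapply(fine, clashAt, numeric(1))
    kF <- which.min(abs(clF - targetClash))
    if (abs(clF[kF] - targetClash) > 0.1 * targetClash)
      .stopf("target clash %.2f unreachable for this complex (closest %.2f)",
             targetClash, clF[kF])
    pose <- mkPose(sweep(lig, 2, c(fine[kF], 0, 0), "+"))
    pose@clashScore <- poseClashScore(pose, protein)$total
    list(protein = protein, pose = pose)
  })
}

#' Plant a linear structure-activity relationship
#'
#' Draws sparse binary fingerprints X (independent Bernoulli bits), fixed
#' true weights w ~ Normal(0, weightScale), and labels
#' `y = X w + Normal(0, noiseSd)`. With noise variance s2 and signal
#' variance v the best achievable test R2 is the analytic ceiling
#' `v / (v + s2)`, which parameter-recovery tests compare against.
#'
#' @param seed integer seed.
#' @param nSamples number of rows.
#' @param nbits fingerprint width.
#' @param bitDensity expected fraction of set bits (0 < d < 1).
#' @param weightScale standard deviation of the true weights.
#' @param noiseSd label noise standard deviation (pChEMBL units).
#' @return list (X, y, w), deterministic given `seed`.
#' @export
plantSar <- function(seed = 1L, nSamples = 5000L, nbits = 256L,
                     bitDensity = 0.05, weightScale = 0.3, noiseSd = 0.3) {
  stopifnot(bitDensity > 0, bitDensity < 1, noiseSd >= 0)
  .withSeed(seed, {
    w <- stats::rnorm(nbits, 0, weightScale)
    X <- matrix(stats::rbinom(nSamples * nbits, 1, bitDensity),
                nrow = nSamples)
    y <- as.numeric(X %*% w) + stats::rnorm(nSamples, 0, noiseSd)
    list(X = X, y = y, w = w)
  })
}

#' Generate raw curation tables with planted defects
#'
#' Emits activity, compound and structure tables at toy scale with known
#' fractions of records designed to fail each curation filter: compounds
#' with out-of-range molecular weight, mutant activity records, and
#' structures with too-poor resolution. The expected surviving counts are
#' returned alongside the tables.
#'
#' @param seed integer seed.
#' @param nKinases,nStructuresPerKinase,nCompounds table sizes.
#' @param activitiesPerCompound activity records per compound (spread over
#'   kinases).
#' @param fracMwViolations fraction of compounds planted below the MW
#'   bound.
#' @param fracMutant fraction of activity records flagged as mutant.
#' @param fracBadResolution fraction of structures planted above the
#'   resolution gate.
#' @return list with `activities`, `compounds`, `structures` (data.frames)
#'   and `expected` (planted survival bookkeeping).
#' @export
makeToyBenchmark <- function(seed = 1L, nKinases = 3L,
                             nStructuresPerKinase = 2L, nCompounds = 30L,
                             activitiesPerCompound = 2L,
                             fracMwViolations = 0.1, fracMutant = 0.1,
                             fracBadResolution = 0.25) {
  stopifnot(nKinases >= 1L, nStructuresPerKinase >= 1L, nCompounds >= 1L,
            activitiesPerCompound >= 1L)
  .withSeed(seed, {
    lib <- toyLigandLibrary()
    groups <- rep(c("TK", "CMGC", "STE"), length.out = nKinases)
    accs <- sprintf("KIN%03d", seq_len(nKinases))

    compoundIds <- sprintf("CPD%04d", seq_len(nCompounds))
    nBad <- round(fracMwViolations * nCompounds)
    badMw <- if (nBad) seq_len(nBad) else integer(0)  # planted, not sampled
    mw <- stats::runif(nCompounds, 300, 700)
    mw[badMw] <- stats::runif(length(badMw), 100, 240)
    comps <- data.frame(
      compound_id = compoundIds,
      smiles = rep(lib, length.out = nCompounds),
      mw = mw,
      hbd = sample(0:5, nCompounds, replace = TRUE),
      hba = sample(0:10, nCompounds, replace = TRUE),
      rotb = sample(0:12, nCompounds, replace = TRUE),
      stringsAsFactors = FALSE)

    nAct <- nCompounds * activitiesPerCompound
    acts <- data.frame(
      compound_id = rep(compoundIds, each = activitiesPerCompound),
      accession = accs[1L + (seq_len(nAct) - 1L) %% nKinases],
      pchembl = pmin(12, pmax(2, stats::rnorm(nAct, 6.5, 1))),
      activity_type = sample(c("pIC50", "pKi", "pKd"), nAct, replace = TRUE),
      is_mutant = FALSE, stringsAsFactors = FALSE)
    nMut <- round(fracMutant * nAct)
    if (nMut) acts$is_mutant[seq_len(nMut)] <- TRUE

    nStruct <- nKinases * nStructuresPerKinase
    states <- expand.grid(dfg = c("in", "out"), ac = c("in", "out"),
                          stringsAsFactors = FALSE)
    structRows <- list()
    sid <- 0L
    for (k in seq_len(nKinases)) for (s in seq_len(nStructuresPerKinase)) {
      sid <- sid + 1L
      st <- states[1L + (s - 1L) %% nrow(states), ]
      toy <- makeToyComplex(seed = seed * 1000L + sid, nProteinAtoms = 40L,
                            nLigandAtoms = 5L, targetClash = 0)
      structRows[[sid]] <- data.frame(
        structure_id = sprintf("STR%03d", sid), accession = accs[k],
        pdb_code = sprintf("%04X", 4096L + sid),
        resolution = stats::runif(1, 1.5, 2.4),
        quality_score = stats::runif(1, 8, 10),
        missing_residues = sample(0:5, 1),
        dfg_state = st$dfg, ac_helix_state = st$ac,
        kinase_group = groups[k],
        pdb_text = writeProteinPdb(toy$protein),
        stringsAsFactors = FALSE)
    }
    structs <- do.call(rbind, structRows)
    nBadRes <- round(fracBadResolution * nStruct)
    if (nBadRes) structs$resolution[seq_len(nBadRes)] <-
      stats::runif(nBadRes, 2.6, 3.5)

    expected <- list(
      surviving_compounds = nCompounds - length(badMw),
      failing_compounds = length(badMw),
      mutant_records = nMut,
      surviving_structures = nStruct - nBadRes)
    list(activities = acts, compounds = comps, structures = structs,
         expected = expected)
  })
}
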