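# SMILES-to-prediction orchestration: isomer enumeration, docking through
# the engine contract, clash filtering, PLEC encoding, network scoring and
# flat-mean aggregation, with everything persisted in the pose database.

#' Aggregate per-pose scores into one affinity estimate
#'
#' Within each (structure, isomer) group the `topK` poses by engine rank
#' are kept; the returned estimate is the flat arithmetic mean over all
#' retained scores across structures and isomers (not a mean of group
#' means). Averaging the top-ranked poses over all structures and isomers
#' was the best-performing aggregation in the underlying benchmark.
#'
#' @param perPose data.frame with columns `structure_id`, `isomer_id`,
#'   `rank`, `score`.
#' @param topK poses kept per (structure, isomer) group (default 3).
#' @param hierarchical if `TRUE`, return the mean of per-group means
#'   instead of the flat mean.
#' @return the aggregated score.
#' @export
aggregatePrediction <- function(perPose, topK = 3L, hierarchical = FALSE) {
  if (!nrow(perPose)) stop("no per-pose scores to aggregate")
  grp <- paste(perPose$structure_id, perPose$isomer_id, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(perPose)), grp), function(idx) {
    idx[order(perPose$rank[idx])][seq_len(min(topK, length(idx)))]
  }), use.names = FALSE)
  kept <- perPose[keep, , drop = FALSE]
  if (hierarchical) {
    mean(vapply(split(kept$score, paste(kept$structure_id, kept$isomer_id)),
                mean, numeric(1)))
  } else mean(kept$score)
}

#' Compare pose-aggregation strategies
#'
#' Computes the prediction R2 of four aggregation strategies -- top-ranked
#' pose only, mean of top 2, mean of top 3, mean of all poses -- on the
#' same set of (compound, kinase) pairs.
#'
#' @param perPose data.frame with columns `pair_id`, `structure_id`,
#'   `isomer_id`, `rank`, `score`.
#' @param observed named numeric vector of observed values keyed by
#'   `pair_id`.
#' @return data.frame (strategy, r_squared) with exactly four rows.
#' @export
evaluateAggregationStrategies <- function(perPose, observed) {
  pairs <- unique(perPose$pair_id)
  if (length(pairs) < 2L) stop("at least 2 pairs required")
  strategies <- list(top1 = 1L, top2_mean = 2L, top3_mean = 3L,
                     all_mean = .Machine$integer.max)
  out <- lapply(names(strategies), function(nm) {
    k <- strategies[[nm]]
    pred <- vapply(pairs, function(p)
      aggregatePrediction(perPose[perPose$pair_id == p, , drop = FALSE],
                          topK = k), numeric(1))
    data.frame(strategy = nm, r_squared = rSquared(pred, observed[pairs]))
  })
  do.call(rbind, out)
}

#' Run the docking and prediction pipeline
#'
#' For each input compound: enumerate stereoisomers, dock every isomer
#' into every structure of the requested kinases through the engine
#' contract, filter poses by clash score, PLEC-encode the top surviving
#' poses, score them with the network, and aggregate to one predicted
#' pChEMBL per (compound, kinase) pair. All poses (with clash scores) are
#' persisted in the pose database; poses already stored for an
#' (isomer, structure, engine) combination are reused rather than
#' re-docked, so repeated runs against the same database are exactly
#' reproducible.
#'
#' @param smiles character vector of compound SMILES.
#' @param accessions kinase accessions to predict against (must exist in
#'   the database).
#' @param engine a [DockingEngine-class].
#' @param db a [PoseDB-class] holding the curated structures.
#' @param model a trained [ScoringNetwork-class] (PLEC width).
#' @param nPoses maximum poses per (isomer, structure) (default 5).
#' @param clashThreshold pose acceptance threshold (default 10).
#' @param topK poses aggregated per (structure, isomer) (default 3).
#' @param maxIsomers isomer cap per compound (default 8 at pipeline level).
#' @param plecParams list of [plec()] parameters (depths, cutoff; width is
#'   taken from the model).
#' @param seed integer seed driving the engine.
#' @return list of [PredictionRecord-class], one per (compound, kinase);
#'   compounds with unparsable SMILES yield records with status
#'   `"invalid_smiles"`, pairs whose every pose fails the clash filter
#'   status `"no_valid_pose"`.
#' @export
runPipeline <- function(smiles, accessions, engine, db, model,
                        nPoses = 5L, clashThreshold = 10, topK = 3L,
                        maxIsomers = 8L, plecParams = list(), seed = 1L) {
  .dbCheckOpen(db)
  structAll <- dbLoad(db, "structures")
  known <- unique(structAll$accession)
  bad <- setdiff(accessions, known)
  if (length(bad))
    .stopf("unknown accession(s) %s; database holds: %s",
           paste(bad, collapse = ", "), paste(known, collapse = ", "))
  pp <- utils::modifyList(list(depthLigand = 2L, depthProtein = 4L,
                               cutoff = 4.5), plecParams)
  records <- list()
  for (smi in smiles) {
    can <- tryCatch(canonicalSmiles(smi), error = function(e) NA_character_)
    if (is.na(can)) {
      for (acc in accessions)
        records[[length(records) + 1L]] <- new(
          "PredictionRecord", smiles = smi, accession = acc,
          engine = engine@name, status = "invalid_smiles",
          perPose = data.frame(), avgScore = NA_real_)
      next
    }
    compoundId <- sprintf("cpd-%010.0f", .fnv1a32(can))
    if (!nrow(dbLoad(db, "compounds", "compound_id = ?", list(compoundId)))) {
      desc <- computeDescriptors(can)
      dbStore(db, "compounds",
              data.frame(compound_id = compoundId, smiles = can,
                         mw = desc$mw, hbd = desc$hbd, hba = desc$hba,
                         rotb = desc$rotb))
    }
    isomers <- enumerateIsomers(can, maxIsomers = maxIsomers)
    isoIds <- sprintf("%s-iso%02d", compoundId, seq_along(isomers))
    for (k in seq_along(isomers)) {
      if (!nrow(dbLoad(db, "isomers", "isomer_id = ?", list(isoIds[k]))))
        dbStore(db, "isomers",
                data.frame(isomer_id = isoIds[k], compound_id = compoundId,
                           isomeric_smiles = isomers[k]))
    }
    for (acc in accessions) {
      structRows <- structAll[structAll$accession == acc, , drop = FALSE]
      perPose <- list()
      for (si in seq_len(nrow(structRows))) {
        srow <- structRows[si, ]
        protein <- readProteinPdb(text = srow$pdb_text,
                                  structureId = srow$structure_id)
        protGraph <- proteinToGraph(protein)
        protCoords <- as.matrix(atoms(protein)[, c("x", "y", "z")])
        box <- makeBox(protCoords, padding = 5)
        for (k in seq_along(isomers)) {
          stored <- dbLoad(db, "poses",
                           "isomer_id = ? AND structure_id = ? AND engine = ?",
                           list(isoIds[k], srow$structure_id, engine@name))
          if (!nrow(stored)) {
            poseSeed <- (seed * 10000L + .fnv1a32(paste(isoIds[k],
                         srow$structure_id)) %% 9973L) %% 2147483647L
            docked <- dockIsomer(engine, isomers[k], protein, box,
                                 nPoses = nPoses, seed = poseSeed)
            for (r in seq_along(docked))
              docked[[r]]@clashScore <- poseClashScore(docked[[r]], protein)$total
            if (length(docked))
              dbStore(db, "poses", data.frame(
                pose_id = sprintf("%s|%s|%s|%d", isoIds[k],
                                  srow$structure_id, engine@name,
                                  vapply(docked, function(p) p@rank,
                                         integer(1))),
                isomer_id = isoIds[k],
                structure_id = srow$structure_id,
                engine = engine@name,
                rank = vapply(docked, function(p) p@rank, integer(1)),
                engine_score = vapply(docked, function(p) p@engineScore,
                                      numeric(1)),
                clash_score = vapply(docked, function(p) p@clashScore,
                                     numeric(1)),
                molblock = vapply(docked, writePoseMol, character(1)),
                stringsAsFactors = FALSE))
            # scoring always uses the persisted representation, so fresh
            # runs and database re-runs follow one identical code path
            stored <- dbLoad(db, "poses",
                             "isomer_id = ? AND structure_id = ? AND engine = ?",
                             list(isoIds[k], srow$structure_id, engine@name))
          }
          poses <- lapply(seq_len(nrow(stored)), function(r)
            readPoseMol(stored$molblock[r], poseId = stored$pose_id[r],
                        isomerId = stored$isomer_id[r],
                        structureId = stored$structure_id[r],
                        engine = stored$engine[r], rank = stored$rank[r],
                        engineScore = stored$engine_score[r]))
          for (r in seq_along(poses))
            poses[[r]]@clashScore <- stored$clash_score[r]
          kept <- filterPoses(poses, threshold = clashThreshold)
          if (!length(kept)) next
          kept <- kept[order(vapply(kept, function(p) p@rank, integer(1)))]
          kept <- kept[seq_len(min(topK, length(kept)))]
          for (p in kept) {
            fp <- plec(p@graph, poseCoords(p), protGraph, protCoords,
                       depthLigand = pp$depthLigand,
                       depthProtein = pp$depthProtein, cutoff = pp$cutoff,
                       nbits = model@inputBits)
            sc <- predictAffinity(model, denseVector(fp))
            perPose[[length(perPose) + 1L]] <- data.frame(
              structure_id = srow$structure_id, isomer_id = isoIds[k],
              rank = p@rank, score = sc, stringsAsFactors = FALSE)
          }
        }
      }
      if (!length(perPose)) {
        records[[length(records) + 1L]] <- new(
          "PredictionRecord", smiles = can, accession = acc,
          engine = engine@name, status = "no_valid_pose",
          perPose = data.frame(), avgScore = NA_real_)
      } else {
        ppDf <- do.call(rbind, perPose)
        records[[length(records) + 1L]] <- new(
          "PredictionRecord", smiles = can, accession = acc,
          engine = engine@name, status = "ok", perPose = ppDf,
          avgScore = aggregatePrediction(ppDf, topK = topK))
      }
    }
  }
  records
}

#' Dock every curated compound into its kinases' structures
#'
#' Batch docking over a populated pose database: for every stored activity
#' pair, the compound's stereoisomers (enumerated and persisted on first
#' use) are docked into every structure of the kinase through the engine
#' contract, clash scores are computed, and the ranked poses stored.
#' Combinations already docked with this engine are skipped.
#'
#' @param db a [PoseDB-class] populated with compounds, activities and
#'   structures (see [dbStoreDataset()]).
#' @param engine a [DockingEngine-class].
#' @param nPoses maximum poses per (isomer, structure) (default 5).
#' @param maxIsomers isomer cap per compound (default 8).
#' @param seed integer seed.
#' @return invisibly, a data.frame summary (n_isomers, n_new_poses).
#' @export
dockDatabase <- function(db, engine, nPoses = 5L, maxIsomers = 8L, seed = 1L) {
  .dbCheckOpen(db)
  acts <- dbLoad(db, "activities")
  comps <- dbLoad(db, "compounds")
  structAll <- dbLoad(db, "structures")
  newPoses <- 0L; nIso <- 0L
  for (cid in unique(acts$compound_id)) {
    smi <- comps$smiles[comps$compound_id == cid][1]
    isoRows <- dbLoad(db, "isomers", "compound_id = ?", list(cid))
    if (!nrow(isoRows)) {
      isomers <- enumerateIsomers(smi, maxIsomers = maxIsomers)
      isoRows <- data.frame(isomer_id = sprintf("%s-iso%02d", cid,
                                                seq_along(isomers)),
                            compound_id = cid, isomeric_smiles = isomers,
                            stringsAsFactors = FALSE)
      dbStore(db, "isomers", isoRows)
    }
    nIso <- nIso + nrow(isoRows)
    for (acc in unique(acts$accession[acts$compound_id == cid])) {
      for (sid in structAll$structure_id[structAll$accession == acc]) {
        srow <- structAll[structAll$structure_id == sid, ]
        protein <- readProteinPdb(text = srow$pdb_text, structureId = sid)
        box <- makeBox(as.matrix(atoms(protein)[, c("x", "y", "z")]),
                       padding = 5)
        for (k in seq_len(nrow(isoRows))) {
          isoId <- isoRows$isomer_id[k]
          if (nrow(dbLoad(db, "poses",
                          "isomer_id = ? AND structure_id = ? AND engine = ?",
                          list(isoId, sid, engine@name)))) next
          poseSeed <- (seed * 10000L +
                       .fnv1a32(paste(isoId, sid)) %% 9973L) %% 2147483647L
          docked <- dockIsomer(engine, isoRows$isomeric_smiles[k], protein,
                               box, nPoses = nPoses, seed = poseSeed)
          for (r in seq_along(docked))
            docked[[r]]@clashScore <- poseClashScore(docked[[r]], protein)$total
          if (length(docked)) {
            dbStore(db, "poses", data.frame(
              pose_id = sprintf("%s|%s|%s|%d", isoId, sid, engine@name,
                                vapply(docked, function(p) p@rank,
                                       integer(1))),
              isomer_id = isoId, structure_id = sid, engine = engine@name,
              rank = vapply(docked, function(p) p@rank, integer(1)),
              engine_score = vapply(docked, function(p) p@engineScore,
                                    numeric(1)),
              clash_score = vapply(docked, function(p) p@clashScore,
                                   numeric(1)),
              molblock = vapply(docked, writePoseMol, character(1)),
              stringsAsFactors = FALSE))
            newPoses <- newPoses + length(docked)
          }
        }
      }
    }
  }
  invisible(data.frame(n_isomers = nIso, n_new_poses = newPoses))
}

#' PLEC-encode the stored poses of a database
#'
#' Computes the PLEC fingerprint of every clash-accepted stored pose
#' (top `topK` by engine rank per (isomer, structure)).
#'
#' @inheritParams dockDatabase
#' @param engineName engine whose poses to encode.
#' @param clashThreshold pose acceptance threshold (default 10).
#' @param topK poses per (isomer, structure) group (default 3).
#' @param nbits,depthLigand,depthProtein,cutoff [plec()] parameters.
#' @return data.frame with one row per encoded pose: `pose_id`,
#'   `isomer_id`, `structure_id`, `rank`, `compound_id`, `accession`, and a
#'   list column `bits` of set-bit indices.
#' @export
fingerprintDatabase <- function(db, engineName = "mock", clashThreshold = 10,
                                topK = 3L, nbits = 65536L, depthLigand = 2L,
                                depthProtein = 4L, cutoff = 4.5) {
  .dbCheckOpen(db)
  poses <- dbLoad(db, "poses", "engine = ?", list(engineName))
  if (!nrow(poses)) return(data.frame())
  poses <- poses[poses$clash_score < clashThreshold, , drop = FALSE]
  grp <- paste(poses$isomer_id, poses$structure_id, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(poses)), grp), function(idx)
    idx[order(poses$rank[idx])][seq_len(min(topK, length(idx)))]),
    use.names = FALSE)
  poses <- poses[sort(keep), , drop = FALSE]
  isoAll <- dbLoad(db, "isomers")
  structAll <- dbLoad(db, "structures")
  protCache <- list()
  out <- vector("list", nrow(poses))
  for (r in seq_len(nrow(poses))) {
    sid <- poses$structure_id[r]
    if (is.null(protCache[[sid]])) {
      srow <- structAll[structAll$structure_id == sid, ]
      protein <- readProteinPdb(text = srow$pdb_text, structureId = sid)
      protCache[[sid]] <- list(
        graph = proteinToGraph(protein),
        coords = as.matrix(atoms(protein)[, c("x", "y", "z")]),
        accession = srow$accession)
    }
    pc <- protCache[[sid]]
    pose <- readPoseMol(poses$molblock[r], poseId = poses$pose_id[r])
    fp <- plec(pose@graph, poseCoords(pose), pc$graph, pc$coords,
               depthLigand = depthLigand, depthProtein = depthProtein,
               cutoff = cutoff, nbits = nbits)
    out[[r]] <- data.frame(
      pose_id = poses$pose_id[r], isomer_id = poses$isomer_id[r],
      structure_id = sid, rank = poses$rank[r],
      compound_id = isoAll$compound_id[match(poses$isomer_id[r],
                                             isoAll$isomer_id)],
      accession = pc$accession, stringsAsFactors = FALSE)
    out[[r]]$bits <- list(bitIndices(fp))
  }
  res <- do.call(rbind, out)
  attr(res, "nbits") <- nbits
  res
}

#' Train the scoring network from a pose database
#'
#' The database-level training workflow: PLEC fingerprints of the
#' clash-accepted top-ranked poses are paired with their activity's
#' averaged pChEMBL, the activity pairs are split leakage-aware
#' ([makeSplits()]), and the network is trained on the per-pose rows (every
#' pose of a pair inherits the pair's label and split side). The held-out
#' metric is also reported after flat-mean aggregation per pair.
#'
#' @inheritParams fingerprintDatabase
#' @param strategy split strategy passed to [makeSplits()].
#' @param spec a [scoringNetworkSpec()]; its width sets the PLEC width.
#' @param config a [trainingConfig()].
#' @param testFraction held-out fraction (default 0.2).
#' @return list: `model` ([ScoringNetwork-class]), `split`
#'   ([SplitAssignment-class]), `testR2pose` (per-pose held-out R2),
#'   `testR2aggregated` (per-pair R2 after flat-mean aggregation; `NA` with
#'   fewer than 2 test pairs), `nTrainPoses`, `nTestPoses`.
#' @export
trainFromDatabase <- function(db, engineName = "mock",
                              strategy = c("random", "compound", "kinase"),
                              spec = scoringNetworkSpec(65536L),
                              config = trainingConfig(),
                              clashThreshold = 10, topK = 3L,
                              depthLigand = 2L, depthProtein = 4L,
                              cutoff = 4.5, testFraction = 0.2) {
  strategy <- match.arg(strategy)
  fps <- fingerprintDatabase(db, engineName, clashThreshold, topK,
                             nbits = spec$inputBits,
                             depthLigand = depthLigand,
                             depthProtein = depthProtein, cutoff = cutoff)
  if (!nrow(fps)) stop("no clash-accepted poses to train on")
  acts <- dbLoad(db, "activities")
  acts$activity_id <- paste(acts$compound_id, acts$accession, sep = "|")
  fps$activity_id <- paste(fps$compound_id, fps$accession, sep = "|")
  fps <- fps[fps$activity_id %in% acts$activity_id, , drop = FALSE]
  actsUsed <- acts[acts$activity_id %in% fps$activity_id, , drop = FALSE]
  split <- makeSplits(actsUsed, strategy, testFraction, seed = config$seed)
  toX <- function(rows) {
    X <- matrix(0, nrow(rows), spec$inputBits)
    for (i in seq_len(nrow(rows))) X[i, rows$bits[[i]] + 1L] <- 1
    X
  }
  lab <- stats::setNames(actsUsed$pchembl, actsUsed$activity_id)
  trRows <- fps[fps$activity_id %in% split@trainIds, , drop = FALSE]
  teRows <- fps[fps$activity_id %in% split@testIds, , drop = FALSE]
  if (!nrow(trRows) || !nrow(teRows))
    stop("split left one side without poses; enlarge the dataset")
  model <- trainScoringNetwork(spec, toX(trRows), lab[trRows$activity_id],
                               toX(teRows), lab[teRows$activity_id], config)
  posePred <- predictAffinity(model, toX(teRows))
  r2pose <- if (nrow(teRows) >= 2L && stats::sd(lab[teRows$activity_id]) > 0)
    rSquared(posePred, lab[teRows$activity_id]) else NA_real_
  teRows$score <- posePred
  pairs <- unique(teRows$activity_id)
  r2agg <- if (length(pairs) >= 2L) {
    aggPred <- vapply(pairs, function(p)
      aggregatePrediction(teRows[teRows$activity_id == p, , drop = FALSE],
                          topK = topK), numeric(1))
    if (stats::sd(lab[pairs]) > 0) rSquared(aggPred, lab[pairs]) else NA_real_
  } else NA_real_
  list(model = model, split = split, testR2pose = r2pose,
       testR2aggregated = r2agg, nTrainPoses = nrow(trRows),
       nTestPoses = nrow(teRows))
}

#' Write prediction records as CSV
#'
#' Columns: smiles, accession, engine, status, n_poses, avg_score
#' (predicted pChEMBL; empty for failed records). Output is byte-stable
#' for identical inputs.
#'
#' @param records list of [PredictionRecord-class].
#' @param path output file.
#' @return invisibly, the data.frame written.
#' @export
writePredictionsCsv <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r) data.frame(
    smiles = r@smiles, accession = r@accession, engine = r@engine,
    status = r@status, n_poses = nrow(r@perPose),
    avg_score = if (is.na(r@avgScore)) "" else sprintf("%.6f", r@avgScore),
    stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
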