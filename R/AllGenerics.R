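#' @name kindock-accessors
#' @title Accessors for kindock classes
#' @description Slot accessors; user code should use these rather than `@`.
#' @param x an object.
#' @param object an object (for `show` methods).
NULL

#' @rdname kindock-accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname kindock-accessors
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))

#' @rdname kindock-accessors
#' @export
setGeneric("poseCoords", function(x) standardGeneric("poseCoords"))

#' @rdname kindock-accessors
#' @export
setGeneric("nbits", function(x) standardGeneric("nbits"))

#' @rdname kindock-accessors
#' @export
setGeneric("bitIndices", function(x) standardGeneric("bitIndices"))

#' @rdname kindock-accessors
#' @export
setGeneric("compounds", function(x) standardGeneric("compounds"))

#' @rdname kindock-accessors
#' @export
setGeneric("activities", function(x) standardGeneric("activities"))

#' @rdname kindock-accessors
#' @export
setGeneric("structures", function(x) standardGeneric("structures"))

#' Dock one prepared isomer
#'
#' Engine contract: generate up to `nPoses` ranked poses of `isomer` in
#' `structure`, deterministically for a given `seed` where the engine
#' supports it.
#'
#' @param engine a [DockingEngine-class] adapter.
#' @param isomer isomeric SMILES of the prepared ligand.
#' @param structure a [ProteinStructure-class].
#' @param box a [DockingBox-class], or `NULL` for engines that do blind
#'   docking (`needsBox` slot `FALSE`).
#' @param nPoses maximum number of poses (the pipeline default is 5).
#' @param seed integer seed.
#' @return list of [LigandPose-class], ranks `1..k` without gaps,
#'   `k <= nPoses`.
#' @export
setGeneric("dockIsomer",
           function(engine, isomer, structure, box = NULL, nPoses = 5L, seed = 1L)
             standardGeneric("dockIsomer"))

## ---- accessor methods ----

#' @rdname kindock-accessors
#' @export
setMethod("atoms", "MolGraph", function(x) x@atoms)
#' @rdname kindock-accessors
#' @export
setMethod("bonds", "MolGraph", function(x) x@bonds)
#' @rdname kindock-accessors
#' @export
setMethod("atoms", "ProteinStructure", function(x) x@atoms)
#' @rdname kindock-accessors
#' @export
setMethod("atoms", "LigandPose", function(x) x@graph@atoms)
#' @rdname kindock-accessors
#' @export
setMethod("bonds", "LigandPose", function(x) x@graph@bonds)
#' @rdname kindock-accessors
#' @export
setMethod("poseCoords", "LigandPose", function(x) x@coords)
#' @rdname kindock-accessors
#' @export
setMethod("nbits", "Fingerprint", function(x) x@nbits)
#' @rdname kindock-accessors
#' @export
setMethod("bitIndices", "Fingerprint", function(x) x@bits)
#' @rdname kindock-accessors
#' @export
setMethod("compounds", "CuratedDataset", function(x) x@compounds)
#' @rdname kindock-accessors
#' @export
setMethod("activities", "CuratedDataset", function(x) x@activities)
#' @rdname kindock-accessors
#' @export
setMethod("structures", "CuratedDataset", function(x) x@structures)

## ---- show methods ----

setMethod("show", "MolGraph", function(object) {
  cat("MolGraph:", nrow(object@atoms), "atoms,", nrow(object@bonds), "bonds\n")
  cat("  formula-ish:", paste0(names(table(object@atoms$element)),
                               table(object@atoms$element), collapse = " "), "\n")
})

setMethod("show", "Fingerprint", function(object) {
  cat(sprintf("Fingerprint: %d/%d bits set\n", length(object@bits), object@nbits))
})

setMethod("show", "ProteinStructure", function(object) {
  cat(sprintf("ProteinStructure '%s': %d atoms, %d residues\n",
              object@structureId, nrow(object@atoms),
              length(unique(object@atoms$resno))))
})

setMethod("show", "LigandPose", function(object) {
  cat(sprintf("LigandPose '%s' (isomer %s in %s, engine %s, rank %d)\n",
              object@poseId, object@isomerId, object@structureId,
              object@engine, object@rank))
  cat(sprintf("  %d atoms; engine score %.3f; clash %s\n",
              nrow(object@coords), object@engineScore,
              ifelse(is.na(object@clashScore), "not computed",
                     sprintf("%.3f A", object@clashScore))))
})

setMethod("show", "CuratedDataset", function(object) {
  cat(sprintf("CuratedDataset: %d compounds, %d activities, %d structures (%d kinases)\n",
              nrow(object@compounds), nrow(object@activities),
              nrow(object@structures), length(unique(object@structures$accession))))
})

setMethod("show", "DruglikenessRules", function(object) {
  cat(sprintf("DruglikenessRules: MW [%g, %g] Da; HBD <= %g; HBA <= %g; RotB <= %g (inclusive)\n",
              object@mwMin, object@mwMax, object@hbdMax, object@hbaMax, object@rotbMax))
})

setMethod("show", "ScoringNetwork", function(object) {
  cat(sprintf("ScoringNetwork: %d -> %d -> %d -> 1 (dropout %.2f)\n",
              object@inputBits, object@hidden[1], object@hidden[2], object@dropout))
  if (object@bestEpoch > 0L)
    cat(sprintf("  best checkpoint: epoch %d, test metric %.4f\n", object@bestEpoch,
                object@history$test_metric[object@bestEpoch]))
  else cat("  untrained\n")
})

setMethod("show", "SplitAssignment", function(object) {
  n <- length(object@trainIds) + length(object@testIds)
  cat(sprintf("SplitAssignment (%s): %d train / %d test of %d; KS = %.4f (best of %d candidates)\n",
              object@strategy, length(object@trainIds), length(object@testIds),
              n, object@ks, length(object@candidateKs)))
})

setMethod("show", "PoseDB", function(object) {
  cat("PoseDB at", object@path, "\n")
  if (DBI::dbIsValid(object@con)) {
    for (t in c("proteins", "structures", "compounds", "isomers", "activities", "poses")) {
      n <- DBI::dbGetQuery(object@con, paste0("SELECT COUNT(*) AS n FROM ", t))$n
      cat(sprintf("  %-11s %d rows\n", t, n))
    }
  } else cat("  (connection closed)\n")
})

setMethod("show", "PredictionRecord", function(object) {
  cat(sprintf("PredictionRecord %s x %s [%s]: %s\n", object@smiles,
              object@accession, object@engine,
              if (object@status == "ok") sprintf("predicted pChEMBL %.3f from %d poses",
                                                 object@avgScore, nrow(object@perPose))
              else object@status))
})

setMethod("show", "DockingEngine", function(object) {
  cat(sprintf("DockingEngine '%s' (needs box: %s)\n", object@name, object@needsBox))
})
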