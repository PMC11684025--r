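# Biochemical and structural curation.

#' Drug-likeness rule set constructor
#'
#' Inclusive bounds on molecular weight, H-bond donors/acceptors and
#' rotatable bonds. The defaults are the deliberately lax filters used to
#' keep the more drug-like small molecules: MW 250-750 Da, HBD <= 10,
#' HBA <= 15, RotB <= 15.
#'
#' @param mwMin,mwMax molecular weight bounds (Da).
#' @param hbdMax,hbaMax,rotbMax descriptor maxima.
#' @return a [DruglikenessRules-class].
#' @export
druglikenessRules <- function(mwMin = 250, mwMax = 750, hbdMax = 10,
                              hbaMax = 15, rotbMax = 15) {
  new("DruglikenessRules", mwMin = mwMin, mwMax = mwMax, hbdMax = hbdMax,
      hbaMax = hbaMax, rotbMax = rotbMax)
}

#' Compute drug-likeness descriptors from SMILES
#'
#' Molecular weight, H-bond donor and acceptor counts via OpenBabel's
#' default definitions, rotatable bonds by SMARTS match (single acyclic
#' bonds between non-terminal heavy atoms, triple-bond neighbors excluded).
#'
#' @param smiles character vector of SMILES.
#' @return data.frame (smiles, mw, hbd, hba, rotb).
#' @export
computeDescriptors <- function(smiles) {
  rot <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"
  out <- lapply(smiles, function(s) {
    sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(s)),
                    error = function(e) NULL)
    if (is.null(sdf)) return(data.frame(smiles = s, mw = NA_real_,
                                        hbd = NA_integer_, hba = NA_integer_,
                                        rotb = NA_integer_))
    p <- ChemmineR::propOB(sdf)
    rb <- ChemmineR::smartsSearchOB(sdf, rot, uniqueMatches = TRUE)
    data.frame(smiles = s, mw = p$MW, hbd = as.integer(p$HBD),
               hba = as.integer(p$HBA1), rotb = as.integer(rb))
  })
  do.call(rbind, out)
}

#' Drug-likeness filter
#'
#' Tests compounds against a [DruglikenessRules-class]: pass iff
#' `mwMin <= mw <= mwMax`, `hbd <= hbdMax`, `hba <= hbaMax` and
#' `rotb <= rotbMax`, all bounds inclusive. A compound with any missing
#' descriptor is neither passed nor failed but flagged undetermined (`NA`).
#'
#' @param compounds data.frame with columns `mw`, `hbd`, `hba`, `rotb`
#'   (one row per compound), or a single named list/row.
#' @param rules a [DruglikenessRules-class].
#' @return logical vector: `TRUE` (pass), `FALSE` (fail), `NA`
#'   (undetermined: missing descriptor).
#' @export
filterCompound <- function(compounds, rules = druglikenessRules()) {
  if (!is.data.frame(compounds)) compounds <- as.data.frame(compounds)
  need <- c("mw", "hbd", "hba", "rotb")
  if (!all(need %in% names(compounds)))
    stop("compounds must have columns mw, hbd, hba, rotb")
  ok <- compounds$mw >= rules@mwMin & compounds$mw <= rules@mwMax &
        compounds$hbd <= rules@hbdMax & compounds$hba <= rules@hbaMax &
        compounds$rotb <= rules@rotbMax
  ok  # NA propagates for missing descriptors: the undetermined status
}

#' Aggregate activity records per (compound, kinase) pair
#'
#' Removes mutant-protein measurements, then averages the pChEMBL values of
#' each (compound, accession) group with a plain arithmetic mean. pIC50,
#' pKi and pKd records are pooled indiscriminately.
#'
#' @param records data.frame with columns `compound_id`, `accession`,
#'   `pchembl`, `activity_type`, `is_mutant`.
#' @return data.frame (compound_id, accession, pchembl), one row per pair.
#' @export
aggregateActivities <- function(records) {
  empty <- data.frame(compound_id = character(), accession = character(),
                      pchembl = numeric())
  if (!nrow(records)) return(empty)
  keep <- records[!records$is_mutant, , drop = FALSE]
  if (!nrow(keep)) return(empty)
  agg <- stats::aggregate(pchembl ~ compound_id + accession, data = keep, FUN = mean)
  agg <- agg[order(agg$compound_id, agg$accession), , drop = FALSE]
  rownames(agg) <- NULL
  agg[, c("compound_id", "accession", "pchembl")]
}

#' Select curated kinase structures
#'
#' Removes structures failing the quality gates (resolution, KLIFS-style
#' quality metric, missing residues, applied jointly), then keeps per kinase
#' and per conformational state combination (DFG x alphaC-helix, with
#' "out-like" DFG states folded into "out") the structure with the highest
#' quality score, leaving at most four structures per kinase. Quality ties
#' break by lower resolution, then lexicographic structure id.
#'
#' @param structs data.frame with columns `structure_id`, `accession`,
#'   `resolution`, `quality_score`, `missing_residues`, `dfg_state`,
#'   `ac_helix_state` (and any extra columns, preserved).
#' @param resMax maximum resolution (default 2.5 Angstrom).
#' @param qualityMin minimum quality score (default 8).
#' @param missingMax maximum missing residues (default 5).
#' @return the selected rows of `structs`.
#' @export
selectStructures <- function(structs, resMax = 2.5, qualityMin = 8,
                             missingMax = 5) {
  if (!nrow(structs)) return(structs)
  keep <- structs$resolution <= resMax & structs$quality_score >= qualityMin &
          structs$missing_residues <= missingMax
  s <- structs[keep & !is.na(keep), , drop = FALSE]
  if (!nrow(s)) return(s)
  dfg <- ifelse(s$dfg_state == "out-like", "out", s$dfg_state)
  grp <- paste(s$accession, dfg, s$ac_helix_state, sep = "\r")
  ord <- order(grp, -s$quality_score, s$resolution, s$structure_id)
  s <- s[ord, , drop = FALSE]
  s <- s[!duplicated(grp[ord]), , drop = FALSE]
  s <- s[order(s$accession, s$structure_id), , drop = FALSE]
  rownames(s) <- NULL
  s
}

#' Assemble the curated dataset
#'
#' Composes the three curation steps: drug-likeness filtering of compounds
#' ([filterCompound()]; undetermined compounds are rejected), mutant
#' removal and per-pair averaging of activities ([aggregateActivities()]),
#' and structure selection ([selectStructures()]). Activities are kept only
#' when their compound passed and their kinase retains at least one
#' structure.
#'
#' @param activities data.frame (compound_id, accession, pchembl,
#'   activity_type, is_mutant).
#' @param compounds data.frame (compound_id, smiles, mw, hbd, hba, rotb).
#' @param structs data.frame as for [selectStructures()], additionally with
#'   `pdb_code`, `kinase_group`, `pdb_text` columns where available.
#' @param rules a [DruglikenessRules-class].
#' @param resMax,qualityMin,missingMax structure gates, see
#'   [selectStructures()].
#' @return a [CuratedDataset-class].
#' @export
buildDataset <- function(activities, compounds, structs,
                         rules = druglikenessRules(), resMax = 2.5,
                         qualityMin = 8, missingMax = 5) {
  dupId <- unique(compounds$compound_id[duplicated(compounds$compound_id)])
  for (id in dupId) {
    smi <- unique(compounds$smiles[compounds$compound_id == id])
    if (length(smi) > 1L)
      .stopf("duplicate compound_id '%s' with conflicting SMILES", id)
  }
  compounds <- compounds[!duplicated(compounds$compound_id), , drop = FALSE]
  pass <- filterCompound(compounds, rules)
  comp <- compounds[pass & !is.na(pass), , drop = FALSE]
  selStruct <- selectStructures(structs, resMax, qualityMin, missingMax)
  act <- aggregateActivities(activities)
  act <- act[act$compound_id %in% comp$compound_id &
             act$accession %in% selStruct$accession, , drop = FALSE]
  rownames(comp) <- rownames(act) <- NULL
  new("CuratedDataset", compounds = comp, activities = act,
      structures = selStruct,
      metadata = list(
        rules = rules,
        descriptor_definitions = "OpenBabel defaults (MW, HBD, HBA1); rotatable bonds by SMARTS [!$(*#*)&!D1]-!@[!$(*#*)&!D1]",
        structure_gates = c(resMax = resMax, qualityMin = qualityMin,
                            missingMax = missingMax)))
}

#' Re-export a curated dataset as raw tables
#'
#' Inverse of [buildDataset()] for round-trip checks and for feeding the
#' curated dataset back through the pipeline: activities regain
#' `activity_type`/`is_mutant` columns (averaged records are exported as
#' non-mutant `pIC50` rows).
#'
#' @param dataset a [CuratedDataset-class].
#' @return list of data.frames `activities`, `compounds`, `structures`.
#' @export
exportTables <- function(dataset) {
  act <- activities(dataset)
  act$activity_type <- rep("pIC50", nrow(act))
  act$is_mutant <- rep(FALSE, nrow(act))
  list(activities = act, compounds = compounds(dataset),
       structures = structures(dataset))
}
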