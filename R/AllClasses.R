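#' @import methods
NULL

#' Molecular graph
#'
#' A light molecular graph: one row per atom with the invariants used by the
#' extended-connectivity fingerprints (element, formal charge, aromaticity,
#' attached hydrogen count), and one row per bond. Heavy-atom degree and
#' ring membership are derived on demand (see [heavyDegree()] and
#' [ringMembership()]).
#'
#' @slot atoms data.frame with columns `element` (symbol), `charge`
#'   (integer), `aromatic` (logical), `nH` (attached hydrogens, integer).
#' @slot bonds data.frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (1, 2 or 3; aromatic bonds are kekulized and the aromatic flag
#'   lives on the atoms).
#' @export
setClass("MolGraph", representation(atoms = "data.frame", bonds = "data.frame"))

setValidity("MolGraph", function(object) {
  a <- object@atoms; b <- object@bonds
  if (!all(c("element", "charge", "aromatic", "nH") %in% names(a)))
    return("atoms must have columns element, charge, aromatic, nH")
  if (nrow(a) == 0L) return("empty atom list")
  if (nrow(b) > 0L) {
    if (!all(c("i", "j", "order") %in% names(b)))
      return("bonds must have columns i, j, order")
    if (any(b$i < 1L | b$i > nrow(a) | b$j < 1L | b$j > nrow(a)))
      return("bond indices out of range")
    if (any(b$i == b$j)) return("self-bond")
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    if (anyDuplicated(key)) return("duplicate bond")
  }
  TRUE
})

#' Bit-vector fingerprint
#'
#' Fixed-width binary fingerprint: an ECFP encoding of a molecule or a PLEC
#' encoding of a protein-ligand complex. Only the indices of set bits are
#' stored (0-based, sorted, unique).
#'
#' @slot nbits integer width (2048 for ECFP, 65536 for PLEC by default).
#' @slot bits sorted unique integer indices in `[0, nbits)`.
#' @export
setClass("Fingerprint", representation(nbits = "integer", bits = "integer"))

setValidity("Fingerprint", function(object) {
  if (length(object@nbits) != 1L || object@nbits < 1L) return("invalid nbits")
  b <- object@bits
  if (length(b) && (any(b < 0L) || any(b >= object@nbits))) return("bit index out of range")
  if (is.unsorted(b, strictly = TRUE) && length(b) > 1L) return("bits must be sorted and unique")
  TRUE
})

#' Axis-aligned docking box
#'
#' Search volume for box-guided docking engines, built by [makeBox()] from
#' pocket points plus padding.
#'
#' @slot center numeric xyz center (Angstrom).
#' @slot extents numeric xyz edge lengths (Angstrom), all positive.
#' @export
setClass("DockingBox", representation(center = "numeric", extents = "numeric"))

setValidity("DockingBox", function(object) {
  if (length(object@center) != 3L || length(object@extents) != 3L)
    return("center and extents must be length-3")
  if (!all(is.finite(object@center)) || !all(is.finite(object@extents)))
    return("non-finite box")
  if (any(object@extents <= 0)) return("extents must be positive")
  TRUE
})

#' Protein structure (binding-site atoms)
#'
#' Atom records of one kinase structure as read from a PDB file.
#'
#' @slot structureId opaque identifier.
#' @slot atoms data.frame with columns `element`, `x`, `y`, `z`, `resno`,
#'   `resname`.
#' @export
setClass("ProteinStructure",
         representation(structureId = "character", atoms = "data.frame"))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  if (!all(c("element", "x", "y", "z", "resno", "resname") %in% names(a)))
    return("atoms must have columns element, x, y, z, resno, resname")
  if (nrow(a) == 0L) return("empty atom list")
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")])))) return("non-finite coordinates")
  TRUE
})

#' Docked ligand pose
#'
#' One ranked 3D pose of one stereoisomer docked into one structure, with the
#' engine-native score and (once computed) the steric clash score.
#'
#' @slot poseId,isomerId,structureId opaque identifiers.
#' @slot engine engine label (e.g. "mock", "vina-like", "diffdock-like").
#' @slot rank 1-based engine rank.
#' @slot engineScore engine-native score.
#' @slot clashScore summed van der Waals overlap (Angstrom); `NA` until
#'   computed.
#' @slot graph the molecular graph ([MolGraph-class]).
#' @slot coords numeric matrix (n x 3) of atom coordinates, rows matching
#'   `graph@atoms`.
#' @export
setClass("LigandPose",
         representation(poseId = "character", isomerId = "character",
                        structureId = "character", engine = "character",
                        rank = "integer", engineScore = "numeric",
                        clashScore = "numeric", graph = "MolGraph",
                        coords = "matrix"))

setValidity("LigandPose", function(object) {
  if (object@rank < 1L) return("rank must be >= 1")
  n <- nrow(object@graph@atoms)
  if (!is.numeric(object@coords) || nrow(object@coords) != n || ncol(object@coords) != 3L)
    return("coords must be an n x 3 numeric matrix matching the graph")
  if (!all(is.finite(object@coords))) return("non-finite coordinates")
  TRUE
})

#' Curated activity/structure dataset
#'
#' Output of [buildDataset()]: compounds passing the drug-likeness rules,
#' per-pair averaged activities, and the per-conformation selected
#' structures. Every activity references an existing compound and a kinase
#' with at least one surviving structure; at most one activity per
#' (compound, kinase) pair.
#'
#' @slot compounds data.frame (compound_id, smiles, mw, hbd, hba, rotb).
#' @slot activities data.frame (compound_id, accession, pchembl).
#' @slot structures data.frame (structure_id, accession, pdb_code,
#'   resolution, quality_score, missing_residues, dfg_state, ac_helix_state,
#'   kinase_group, pdb_text).
#' @slot metadata list of provenance notes (descriptor definitions, rule set).
#' @export
setClass("CuratedDataset",
         representation(compounds = "data.frame", activities = "data.frame",
                        structures = "data.frame", metadata = "list"))

setValidity("CuratedDataset", function(object) {
  act <- object@activities
  if (nrow(act)) {
    if (!all(act$compound_id %in% object@compounds$compound_id))
      return("activity references unknown compound")
    if (!all(act$accession %in% object@structures$accession))
      return("activity references kinase without structure")
    if (anyDuplicated(paste(act$compound_id, act$accession)))
      return("more than one activity per (compound, kinase) pair")
  }
  TRUE
})

#' Drug-likeness rule set
#'
#' Inclusive descriptor bounds applied by [filterCompound()]. Defaults are
#' the lax medicinal-chemistry criteria used for the kinase set: molecular
#' weight 250-750 Da, at most 10 H-bond donors, 15 H-bond acceptors and 15
#' rotatable bonds.
#'
#' @slot mwMin,mwMax molecular weight bounds (Da).
#' @slot hbdMax,hbaMax,rotbMax maximum donor/acceptor/rotatable-bond counts.
#' @export
setClass("DruglikenessRules",
         representation(mwMin = "numeric", mwMax = "numeric",
                        hbdMax = "numeric", hbaMax = "numeric",
                        rotbMax = "numeric"))

setValidity("DruglikenessRules", function(object) {
  if (object@mwMin >= object@mwMax) return("mwMin must be < mwMax")
  if (any(c(object@hbdMax, object@hbaMax, object@rotbMax) < 0))
    return("count maxima must be >= 0")
  TRUE
})

#' 3-layer scoring network
#'
#' Fully connected network mapping a fingerprint to a predicted pChEMBL:
#' input -> hidden1 -> hidden2 -> 1, rectified linear activations on the
#' first two layers, linear output. Dropout (training only) on the input and
#' both hidden activations. Returned by [trainScoringNetwork()] as the
#' best-checkpoint model.
#'
#' @slot inputBits fingerprint width the network expects.
#' @slot hidden integer vector of the two hidden widths.
#' @slot dropout dropout rate used during training.
#' @slot weights list W1, b1, W2, b2, W3, b3.
#' @slot bestEpoch epoch of the retained checkpoint (0 = untrained).
#' @slot history data.frame (epoch, train_loss, test_metric).
#' @export
setClass("ScoringNetwork",
         representation(inputBits = "integer", hidden = "integer",
                        dropout = "numeric", weights = "list",
                        bestEpoch = "integer", history = "data.frame"))

setValidity("ScoringNetwork", function(object) {
  if (length(object@hidden) != 2L || any(object@hidden < 1L))
    return("two positive hidden widths required")
  if (object@dropout < 0 || object@dropout >= 1) return("dropout must be in [0, 1)")
  if (object@inputBits < 1L) return("inputBits must be positive")
  TRUE
})

#' Leakage-aware train/test split
#'
#' An 80:20 partition of activity records, by record (`random`) or by whole
#' entity (`compound`, `kinase`), selected among seeded candidate partitions
#' as the one whose train and test pChEMBL distributions are closest
#' (smallest Kolmogorov-Smirnov statistic).
#'
#' @slot strategy "random", "compound" or "kinase".
#' @slot trainIds,testIds disjoint activity identifier sets covering all
#'   records.
#' @slot testFraction target test fraction.
#' @slot ks KS statistic of the returned partition.
#' @slot candidateKs KS statistics of all candidate partitions considered.
#' @export
setClass("SplitAssignment",
         representation(strategy = "character", trainIds = "character",
                        testIds = "character", testFraction = "numeric",
                        ks = "numeric", candidateKs = "numeric"))

setValidity("SplitAssignment", function(object) {
  if (length(intersect(object@trainIds, object@testIds)))
    return("train and test overlap")
  TRUE
})

#' SQLite pose database
#'
#' Handle to the pose database created by [dbInit()]: six relational tables
#' (proteins, structures, compounds, isomers, activities, poses) with
#' enforced foreign keys; pose mol-blocks are stored zlib-compressed.
#'
#' @slot con open DBI connection (SQLite).
#' @slot path database file path.
#' @export
setClass("PoseDB", representation(con = "ANY", path = "character"))

#' Docking engine contract
#'
#' Virtual parent of docking engine adapters. An engine declares whether it
#' needs a search box and implements [dockIsomer()]. The only bundled
#' engine is [mockEngine()]; adapters for external programs plug in behind
#' the same contract.
#'
#' @slot name engine label stored with every pose.
#' @slot needsBox does [dockIsomer()] require a [DockingBox-class]?
#' @export
setClass("DockingEngine",
         representation(name = "character", needsBox = "logical", "VIRTUAL"))

#' @describeIn DockingEngine the deterministic mock engine (see
#'   [mockEngine()]).
#' @export
setClass("MockEngine", contains = "DockingEngine")

#' Per-pair prediction record
#'
#' Result of [runPipeline()] for one (compound, kinase) pair: the per-pose
#' network scores retained for aggregation and their flat mean, the final
#' predicted pChEMBL.
#'
#' @slot smiles input compound SMILES.
#' @slot accession kinase accession.
#' @slot engine docking engine label.
#' @slot status "ok", "invalid_smiles" or "no_valid_pose".
#' @slot perPose data.frame (structure_id, isomer_id, rank, score).
#' @slot avgScore flat mean of the retained per-pose scores (`NA` unless
#'   status is "ok").
#' @export
setClass("PredictionRecord",
         representation(smiles = "character", accession = "character",
                        engine = "character", status = "character",
                        perPose = "data.frame", avgScore = "numeric"))

setValidity("PredictionRecord", function(object) {
  if (object@status == "ok") {
    if (!nrow(object@perPose)) return("ok record without poses")
    if (abs(object@avgScore - mean(object@perPose$score)) > 1e-9)
      return("avgScore does not match perPose scores")
  }
  TRUE
})
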