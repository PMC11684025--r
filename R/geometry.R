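# Docking-box construction and the steric clash score.

# Bondi van der Waals radii (Angstrom)
.VDW <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
          F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, P = 1.80)
.VDW_DEFAULT <- 1.50

#' Van der Waals radius lookup
#'
#' Bondi radii; unknown elements fall back to 1.50 Angstrom with a warning.
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii (Angstrom).
#' @export
vdwRadius <- function(element) {
  r <- .VDW[element]
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(element[is.na(r)]), collapse = ", "),
            "; using default vdW radius ", .VDW_DEFAULT, " A")
    r[is.na(r)] <- .VDW_DEFAULT
  }
  unname(r)
}

#' Build a docking box around pocket points
#'
#' Axis-aligned bounding box of the supplied pocket points, expanded by
#' `padding` on every face; the default 5 Angstrom padding gives the docking
#' engine room around the detected cavity.
#'
#' @param points numeric matrix (n x 3) of pocket point coordinates.
#' @param padding padding per face (Angstrom, >= 0).
#' @return a [DockingBox-class].
#' @export
makeBox <- function(points, padding = 5) {
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("at least one pocket point is required")
  if (ncol(points) != 3L) stop("points must be n x 3")
  if (padding < 0) stop("padding must be >= 0")
  lo <- apply(points, 2, min) - padding
  hi <- apply(points, 2, max) + padding
  new("DockingBox", center = as.numeric((lo + hi) / 2),
      extents = as.numeric(hi - lo))
}

#' Pairwise clash contribution
#'
#' Linear van der Waals overlap of two atoms: `max(0, r1 + r2 - d)`, where
#' `d` is their Euclidean distance and `r1`, `r2` their vdW radii. Zero for
#' non-overlapping spheres, continuous and non-increasing in `d`.
#'
#' @param d distance(s) in Angstrom, >= 0.
#' @param r1,r2 vdW radii in Angstrom, > 0.
#' @return overlap(s) in Angstrom.
#' @export
clashContribution <- function(d, r1, r2) {
  if (any(d < 0)) stop("negative distance")
  if (any(r1 <= 0) || any(r2 <= 0)) stop("radii must be positive")
  pmax(0, r1 + r2 - d)
}

#' Clash score of a docked pose
#'
#' Selects the protein atoms within `selectionCutoff` of any ligand atom
#' (closed boundary), evaluates [clashContribution()] for every
#' (ligand atom, selected protein atom) pair, and sums the contributions.
#' Large totals indicate physically implausible poses; [filterPoses()]
#' applies the acceptance threshold.
#'
#' @param pose a [LigandPose-class].
#' @param protein a [ProteinStructure-class] sharing the pose's frame.
#' @param selectionCutoff protein-atom selection radius around the ligand
#'   (Angstrom, default 4).
#' @return list with elements `pose_id`, `per_pair` (data.frame
#'   ligand_atom, protein_atom, contribution) and `total` (Angstrom).
#' @export
poseClashScore <- function(pose, protein, selectionCutoff = 4) {
  L <- poseCoords(pose)
  pa <- atoms(protein)
  if (nrow(L) == 0L) stop("empty ligand")
  if (nrow(pa) == 0L) stop("empty protein")
  P <- as.matrix(pa[, c("x", "y", "z")])
  # full ligand x protein distance matrix (toy scale: fine dense)
  D <- sqrt(outer(rowSums(L^2), rowSums(P^2), "+") - 2 * L %*% t(P))
  D[!is.finite(D) | D < 0] <- 0  # guard tiny negative round-off under sqrt
  sel <- which(apply(D, 2, min) <= selectionCutoff)
  rl <- vdwRadius(atoms(pose)$element)
  if (length(sel)) {
    rp <- vdwRadius(pa$element[sel])
    contrib <- outer(rl, rp, "+") - D[, sel, drop = FALSE]
    contrib[contrib < 0] <- 0
    idx <- which(contrib > 0, arr.ind = TRUE)
    perPair <- data.frame(ligand_atom = as.integer(idx[, 1]),
                          protein_atom = as.integer(sel[idx[, 2]]),
                          contribution = contrib[idx])
  } else {
    perPair <- data.frame(ligand_atom = integer(), protein_atom = integer(),
                          contribution = numeric())
  }
  list(pose_id = pose@poseId, per_pair = perPair,
       total = sum(perPair$contribution))
}

#' Fit the clash acceptance threshold
#'
#' Fits a normal distribution to a sample of pose clash scores (sample mean
#' and standard deviation) and returns the 3-sigma upper limit `mu + 3*sd`,
#' the data-driven pose acceptance criterion. On the published engine output
#' this calibration gave ~10, the package's default threshold.
#'
#' @param scores numeric clash scores (length >= 2).
#' @return threshold in Angstrom.
#' @export
fitClashThreshold <- function(scores) {
  scores <- as.numeric(scores)
  if (length(scores) < 2L) stop("at least 2 scores required to fit a threshold")
  if (anyNA(scores)) stop("NA clash scores")
  mean(scores) + 3 * stats::sd(scores)
}

#' Filter poses by clash score
#'
#' Retains poses whose clash total is strictly below the threshold
#' (criterion `clash < threshold`), preserving order.
#'
#' @param poses list of [LigandPose-class] with `clashScore` set, or a
#'   numeric vector of clash totals.
#' @param threshold acceptance threshold (Angstrom, default 10).
#' @return the retained poses (same type as input).
#' @export
filterPoses <- function(poses, threshold = 10) {
  if (is.numeric(poses)) return(poses[poses < threshold])
  totals <- vapply(poses, function(p) p@clashScore, numeric(1))
  if (anyNA(totals)) stop("all poses must have a computed clash score")
  poses[totals < threshold]
}
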