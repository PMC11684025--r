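# ECFP and PLEC fingerprints.
#
# Both fingerprints are built on iterative neighborhood hashing: each atom
# carries a depth-0 identifier hashing its invariant tuple (element, formal
# charge, aromaticity, heavy degree, attached H, ring membership) and the
# depth-k identifier hashes the depth-(k-1) identifier together with the
# sorted (bond order, neighbor identifier) list. The hash is a fixed 32-bit
# FNV-1a over the serialised tuple, so fingerprints are bit-identical across
# runs and platforms. ECFP folds the per-atom identifiers into the bit
# vector; PLEC hashes (ligand environment, protein environment) identifier
# pairs for every inter-molecular contact.

# identifier matrix: one row per atom, one column per depth 0..maxDepth
.envMatrix <- function(graph, maxDepth) {
  a <- graph@atoms
  deg <- heavyDegree(graph)
  ring <- ringMembership(graph)
  n <- nrow(a)
  ids <- matrix(0, nrow = n, ncol = maxDepth + 1L)
  ids[, 1] <- .fnv1a32v(sprintf("A|%s|%d|%d|%d|%d|%d", a$element, a$charge,
                                as.integer(a$aromatic), deg, a$nH,
                                as.integer(ring)))
  if (maxDepth == 0L) return(ids)
  b <- graph@bonds
  nbr <- vector("list", n)
  if (nrow(b)) for (k in seq_len(nrow(b))) {
    nbr[[b$i[k]]] <- rbind(nbr[[b$i[k]]], c(b$j[k], b$order[k]))
    nbr[[b$j[k]]] <- rbind(nbr[[b$j[k]]], c(b$i[k], b$order[k]))
  }
  for (d in seq_len(maxDepth)) {
    for (v in seq_len(n)) {
      nb <- nbr[[v]]
      if (is.null(nb)) {
        s <- sprintf("E|%.0f|", ids[v, d])
      } else {
        parts <- sprintf("%d:%.0f", nb[, 2], ids[nb[, 1], d])
        s <- sprintf("E|%.0f|%s", ids[v, d],
                     paste(sort(parts), collapse = ";"))
      }
      ids[v, d + 1L] <- .fnv1a32(s)
    }
  }
  ids
}

#' Atom environment identifiers
#'
#' The per-depth neighborhood identifiers of one atom: depth 0 hashes the
#' atom's invariant tuple, depth k hashes the depth-(k-1) identifier with
#' the sorted (bond order, neighbor identifier) list. Atom relabeling leaves
#' the multiset of identifiers unchanged at every depth.
#'
#' @param graph a [MolGraph-class].
#' @param atom 1-based atom index.
#' @param maxDepth maximum neighborhood radius (>= 0).
#' @return data.frame with columns `depth` (0..maxDepth) and `identifier`
#'   (numeric 32-bit hash values).
#' @export
atomEnvironments <- function(graph, atom, maxDepth) {
  stopifnot(maxDepth >= 0)
  if (atom < 1L || atom > nrow(graph@atoms)) stop("invalid atom index")
  ids <- .envMatrix(graph, maxDepth)
  data.frame(depth = 0:maxDepth, identifier = ids[atom, ])
}

.newFingerprint <- function(idx, nb) {
  new("Fingerprint", nbits = as.integer(nb),
      bits = sort(unique(as.integer(idx))))
}

.checkPow2 <- function(nb) {
  if (nb < 2 || bitwAnd(as.integer(nb), as.integer(nb) - 1L) != 0L)
    stop("nbits must be a power of two")
}

#' Extended-connectivity fingerprint (ECFP)
#'
#' Hashed circular fingerprint of a molecule: every atom environment of
#' depth 0..radius sets bit `identifier mod nbits`. `radius = 2` with 2048
#' bits corresponds to the widely used ECFP4 configuration.
#'
#' @param graph a [MolGraph-class].
#' @param radius neighborhood radius (default 2).
#' @param nbits fingerprint width, a power of two (default 2048).
#' @return a [Fingerprint-class].
#' @export
ecfp <- function(graph, radius = 2L, nbits = 2048L) {
  .checkPow2(nbits)
  ids <- .envMatrix(graph, radius)
  .newFingerprint(ids %% nbits, nbits)
}

#' Inter-molecular heavy-atom contacts
#'
#' All (ligand heavy atom, protein heavy atom) pairs within `cutoff`
#' (closed boundary, pairs at exactly the cutoff are included).
#'
#' @param ligandCoords,proteinCoords numeric n x 3 coordinate matrices.
#' @param ligandElements,proteinElements element symbols per row (hydrogens
#'   are excluded from contact search).
#' @param cutoff contact distance in Angstrom (default 4.5).
#' @return data.frame (ligand_atom, protein_atom, distance).
#' @export
findContacts <- function(ligandCoords, proteinCoords,
                         ligandElements = NULL, proteinElements = NULL,
                         cutoff = 4.5) {
  L <- as.matrix(ligandCoords); P <- as.matrix(proteinCoords)
  li <- seq_len(nrow(L)); pi <- seq_len(nrow(P))
  if (!is.null(ligandElements)) li <- li[ligandElements != "H"]
  if (!is.null(proteinElements)) pi <- pi[proteinElements != "H"]
  if (!length(li) || !length(pi))
    return(data.frame(ligand_atom = integer(), protein_atom = integer(),
                      distance = numeric()))
  D2 <- outer(rowSums(L[li, , drop = FALSE]^2),
              rowSums(P[pi, , drop = FALSE]^2), "+") -
        2 * L[li, , drop = FALSE] %*% t(P[pi, , drop = FALSE])
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  idx <- which(D <= cutoff, arr.ind = TRUE)
  out <- data.frame(ligand_atom = li[idx[, 1]], protein_atom = pi[idx[, 2]],
                    distance = D[idx])
  out[order(out$ligand_atom, out$protein_atom), , drop = FALSE]
}

#' Protein-ligand extended connectivity fingerprint (PLEC)
#'
#' For every heavy-atom contact within `cutoff` and every depth combination
#' `(i <= depthLigand, j <= depthProtein)`, the pair of environment
#' identifiers (ligand at depth i, protein at depth j) is hashed into
#' `[0, nbits)` and the bit set. Invariant under rigid motion of the whole
#' complex (depends only on graphs and inter-atomic distances). The depth
#' and cutoff defaults (2, 4, 4.5 Angstrom) follow the original PLEC
#' formulation.
#'
#' @param ligandGraph,proteinGraph [MolGraph-class] objects (the protein
#'   graph is typically residue-local, see [proteinToGraph()]).
#' @param ligandCoords,proteinCoords coordinate matrices matching the
#'   graphs.
#' @param depthLigand,depthProtein environment depths (defaults 2 and 4).
#' @param cutoff contact cutoff (Angstrom, default 4.5).
#' @param nbits width, a power of two (default 65536).
#' @return a [Fingerprint-class].
#' @export
plec <- function(ligandGraph, ligandCoords, proteinGraph, proteinCoords,
                 depthLigand = 2L, depthProtein = 4L, cutoff = 4.5,
                 nbits = 65536L) {
  .checkPow2(nbits)
  contacts <- findContacts(ligandCoords, proteinCoords,
                           ligandGraph@atoms$element,
                           proteinGraph@atoms$element, cutoff)
  if (!nrow(contacts)) return(.newFingerprint(integer(), nbits))
  idsL <- .envMatrix(ligandGraph, depthLigand)
  idsP <- .envMatrix(proteinGraph, depthProtein)
  combos <- expand.grid(i = 0:depthLigand, j = 0:depthProtein)
  bits <- integer(0)
  for (k in seq_len(nrow(contacts))) {
    la <- contacts$ligand_atom[k]; pa <- contacts$protein_atom[k]
    s <- sprintf("P|%.0f|%.0f", idsL[la, combos$i + 1L], idsP[pa, combos$j + 1L])
    bits <- c(bits, .fnv1a32v(s) %% nbits)
  }
  .newFingerprint(bits, nbits)
}

#' Dense 0/1 vector of a fingerprint
#'
#' @param fp a [Fingerprint-class].
#' @return numeric vector of length `nbits(fp)`.
#' @export
denseVector <- function(fp) {
  v <- numeric(fp@nbits)
  v[fp@bits + 1L] <- 1
  v
}

#' Bitwise OR of fingerprints
#'
#' @param ... [Fingerprint-class] objects of equal width.
#' @return a [Fingerprint-class].
#' @export
fpUnion <- function(...) {
  fps <- list(...)
  nb <- unique(vapply(fps, function(f) f@nbits, integer(1)))
  if (length(nb) != 1L) stop("fingerprint widths differ")
  .newFingerprint(unlist(lapply(fps, function(f) f@bits)), nb)
}

#' Residue-local protein graph
#'
#' Builds a [MolGraph-class] for a protein from atom coordinates, inferring
#' covalent bonds between atoms of the same residue whose distance is below
#' the sum of covalent radii plus a tolerance. Only atoms present in the
#' input contribute: environments never depend on unresolved atoms.
#'
#' @param protein a [ProteinStructure-class].
#' @param tol bond-detection tolerance in Angstrom (default 0.45).
#' @return a [MolGraph-class] with one atom per protein atom (input order).
#' @export
proteinToGraph <- function(protein, tol = 0.45) {
  covr <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07)
  a <- atoms(protein)
  r <- covr[a$element]; r[is.na(r)] <- 0.8
  X <- as.matrix(a[, c("x", "y", "z")])
  bonds <- list()
  for (res in unique(a$resno)) {
    idx <- which(a$resno == res)
    if (length(idx) < 2L) next
    D <- as.matrix(stats::dist(X[idx, , drop = FALSE]))
    thr <- outer(r[idx], r[idx], "+") + tol
    hit <- which(D < thr & upper.tri(D), arr.ind = TRUE)
    if (nrow(hit))
      bonds[[length(bonds) + 1L]] <- data.frame(i = idx[hit[, 1]],
                                                j = idx[hit[, 2]],
                                                order = 1L)
  }
  bondsDf <- if (length(bonds)) do.call(rbind, bonds)
             else data.frame(i = integer(), j = integer(), order = integer())
  new("MolGraph",
      atoms = data.frame(element = a$element, charge = 0L, aromatic = FALSE,
                         nH = 0L, stringsAsFactors = FALSE),
      bonds = bondsDf)
}
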