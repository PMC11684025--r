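# Independent brute-force oracles and small fixture builders shared by the
# test files. The oracles deliberately re-derive quantities with the
# simplest possible loops, without the shortcuts used by the implementation.

# all-pairs clash sum: no 4 A pre-selection, plain double loop
bruteClash <- function(pose, protein) {
  L <- poseCoords(pose)
  pa <- atoms(protein)
  rl <- suppressWarnings(vdwRadius(atoms(pose)$element))
  rp <- suppressWarnings(vdwRadius(pa$element))
  total <- 0
  for (i in seq_len(nrow(L))) for (j in seq_len(nrow(pa))) {
    d <- sqrt(sum((L[i, ] - c(pa$x[j], pa$y[j], pa$z[j]))^2))
    total <- total + max(0, rl[i] + rp[j] - d)
  }
  total
}

# recursive re-derivation of one atom's environment identifier at a depth,
# enumerating the neighborhood subtree explicitly at every level
oracleEnvId <- function(graph, atom, depth) {
  a <- graph@atoms
  deg <- heavyDegree(graph)
  ring <- ringMembership(graph)
  if (depth == 0L)
    return(kindock:::.fnv1a32(sprintf("A|%s|%d|%d|%d|%d|%d",
      a$element[atom], a$charge[atom], as.integer(a$aromatic[atom]),
      deg[atom], a$nH[atom], as.integer(ring[atom]))))
  b <- graph@bonds
  inc <- which(b$i == atom | b$j == atom)
  prev <- oracleEnvId(graph, atom, depth - 1L)
  if (!length(inc)) return(kindock:::.fnv1a32(sprintf("E|%.0f|", prev)))
  parts <- vapply(inc, function(k) {
    nb <- if (b$i[k] == atom) b$j[k] else b$i[k]
    sprintf("%d:%.0f", b$order[k], oracleEnvId(graph, nb, depth - 1L))
  }, character(1))
  kindock:::.fnv1a32(sprintf("E|%.0f|%s", prev, paste(sort(parts), collapse = ";")))
}

# brute-force PLEC: explicit loops over contacts and depth combinations
oraclePlecBits <- function(ligGraph, ligCoords, protGraph, protCoords,
                           depthLigand, depthProtein, cutoff, nb) {
  bits <- integer(0)
  ligEl <- ligGraph@atoms$element
  protEl <- protGraph@atoms$element
  for (i in seq_len(nrow(ligCoords))) {
    if (ligEl[i] == "H") next
    for (j in seq_len(nrow(protCoords))) {
      if (protEl[j] == "H") next
      d <- sqrt(sum((ligCoords[i, ] - protCoords[j, ])^2))
      if (d > cutoff) next
      for (di in 0:depthLigand) for (dj in 0:depthProtein) {
        s <- sprintf("P|%.0f|%.0f", oracleEnvId(ligGraph, i, di),
                     oracleEnvId(protGraph, j, dj))
        bits <- c(bits, kindock:::.fnv1a32(s) %% nb)
      }
    }
  }
  sort(unique(as.integer(bits)))
}

# quick pose builder from bare coordinates (chain graph)
makeChainPose <- function(X, elements = rep("C", nrow(X)),
                          bonds = NULL, poseId = "p", rank = 1L) {
  n <- nrow(X)
  if (is.null(bonds))
    bonds <- if (n > 1L) data.frame(i = seq_len(n - 1L), j = seq_len(n - 1L) + 1L,
                                    order = 1L)
             else data.frame(i = integer(), j = integer(), order = integer())
  g <- new("MolGraph",
           atoms = data.frame(element = elements, charge = 0L, aromatic = FALSE,
                              nH = 0L, stringsAsFactors = FALSE),
           bonds = bonds)
  new("LigandPose", poseId = poseId, isomerId = "iso", structureId = "struct",
      engine = "mock", rank = as.integer(rank), engineScore = 0,
      clashScore = NA_real_, graph = g, coords = X)
}

makeShellProtein <- function(X, elements = rep("C", nrow(X))) {
  new("ProteinStructure", structureId = "prot",
      atoms = data.frame(element = elements, x = X[, 1], y = X[, 2], z = X[, 3],
                         resno = as.integer(ceiling(seq_len(nrow(X)) / 4)),
                         resname = "TOY", stringsAsFactors = FALSE))
}

# a quickly trained tiny PLEC-width model for pipeline tests
tinyPlecModel <- function(nbitsPlec = 1024L, seed = 1L) {
  set.seed(seed)
  X <- matrix(rbinom(8L * nbitsPlec, 1, 0.02), nrow = 8L)
  y <- rnorm(8L, 6.5, 1)
  trainScoringNetwork(scoringNetworkSpec(nbitsPlec, 16L, 8L),
                      X, y, X, y,
                      trainingConfig(learningRate = 1e-3, batchSize = 4L,
                                     epochs = 2L, seed = seed))
}
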