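test_that("atom environments hash the invariant tuple and sorted neighborhoods", {
  lone <- molGraphFromSmiles("C")
  env <- atomEnvironments(lone, 1L, maxDepth = 2L)
  expect_equal(env$depth, 0:2)
  expect_equal(length(unique(env$identifier)), 3L)  # re-hashed each depth
  expect_error(atomEnvironments(lone, 5L, 2L), "invalid atom")

  # multiset of identifiers is invariant under atom relabeling
  g1 <- molGraphFromSmiles("CCO")
  g2 <- molGraphFromSmiles("OCC")
  for (d in 0:2) {
    ids1 <- sort(vapply(seq_len(nrow(atoms(g1))), function(a)
      atomEnvironments(g1, a, d)$identifier[d + 1L], numeric(1)))
    ids2 <- sort(vapply(seq_len(nrow(atoms(g2))), function(a)
      atomEnvironments(g2, a, d)$identifier[d + 1L], numeric(1)))
    expect_equal(ids1, ids2)
  }
})

test_that("environment identifiers match the recursive subtree-enumeration oracle", {
  mols <- c("CCO", "CC(=O)O", "c1ccccc1", "CC(C)CC#N", "CN1CCCC1",
            "OCC(O)CO", "CSC", "FC(F)F")
  for (smi in mols) {
    g <- molGraphFromSmiles(smi)
    for (a in seq_len(nrow(atoms(g)))) for (d in 0:2) {
      expect_equal(atomEnvironments(g, a, d)$identifier[d + 1L],
                   oracleEnvId(g, a, d),
                   info = sprintf("%s atom %d depth %d", smi, a, d))
    }
  }
})

test_that("ECFP is deterministic, order-invariant and discriminates molecules", {
  g <- molGraphFromSmiles("CC(=O)Nc1ccc(O)cc1")
  f1 <- ecfp(g); f2 <- ecfp(g)
  expect_identical(bitIndices(f1), bitIndices(f2))
  expect_lte(length(bitIndices(f1)), nrow(atoms(g)) * 3L)

  # atom-reordered SMILES of the same molecule
  fa <- ecfp(molGraphFromSmiles("Oc1ccc(NC(C)=O)cc1"))
  expect_identical(bitIndices(fa), bitIndices(f1))

  expect_false(identical(bitIndices(ecfp(molGraphFromSmiles("C"))),
                         bitIndices(ecfp(molGraphFromSmiles("CC")))))
  expect_error(ecfp(g, nbits = 1000L), "power of two")
})

test_that("ECFP of a disconnected graph is the OR of its fragments", {
  gBoth <- molGraphFromSmiles("CCO.CC(N)=O")
  gA <- molGraphFromSmiles("CCO")
  gB <- molGraphFromSmiles("CC(N)=O")
  expect_identical(bitIndices(ecfp(gBoth)),
                   bitIndices(fpUnion(ecfp(gA), ecfp(gB))))
})

test_that("contact search equals all-pairs brute force with a closed boundary", {
  set.seed(3)
  L <- matrix(rnorm(60, sd = 3), ncol = 3)
  P <- matrix(rnorm(150, sd = 4), ncol = 3)
  ct <- findContacts(L, P, cutoff = 4.5)
  brute <- list()
  for (i in 1:20) for (j in 1:50) {
    d <- sqrt(sum((L[i, ] - P[j, ])^2))
    if (d <= 4.5) brute[[length(brute) + 1L]] <- c(i, j, d)
  }
  bm <- do.call(rbind, brute)
  expect_equal(nrow(ct), nrow(bm))
  expect_equal(ct$distance, bm[order(bm[, 1], bm[, 2]), 3], tolerance = 1e-9)

  # exactly-at-cutoff pair is included
  ct2 <- findContacts(matrix(c(0, 0, 0), 1), matrix(c(4.5, 0, 0), 1), cutoff = 4.5)
  expect_equal(nrow(ct2), 1L)
  # hydrogens are excluded
  ct3 <- findContacts(matrix(c(0, 0, 0), 1), matrix(c(1, 0, 0), 1),
                      ligandElements = "H", proteinElements = "C")
  expect_equal(nrow(ct3), 0L)
  ct4 <- findContacts(matrix(0, 1, 3), matrix(c(40, 0, 0), 1))
  expect_equal(nrow(ct4), 0L)
})

test_that("PLEC matches the explicit depth-combination oracle on toy complexes", {
  set.seed(17)
  for (rep in 1:12) {
    nl <- sample(3:6, 1); np <- sample(4:10, 1)
    lig <- makeChainPose(matrix(rnorm(3 * nl, sd = 2), ncol = 3),
                         sample(c("C", "N", "O"), nl, TRUE))
    protX <- matrix(rnorm(3 * np, sd = 3), ncol = 3)
    prot <- makeShellProtein(protX, sample(c("C", "N", "O"), np, TRUE))
    pg <- proteinToGraph(prot)
    fp <- plec(lig@graph, poseCoords(lig), pg, protX, depthLigand = 2L,
               depthProtein = 3L, cutoff = 4.5, nbits = 4096L)
    expect_identical(bitIndices(fp),
                     oraclePlecBits(lig@graph, poseCoords(lig), pg, protX,
                                    2L, 3L, 4.5, 4096L))
  }
})

test_that("PLEC is rigid-motion invariant and empty without contacts", {
  lig <- makeChainPose(matrix(rnorm(12), 4), c("C", "N", "C", "O"))
  protX <- matrix(rnorm(24, sd = 2), 8)
  prot <- makeShellProtein(protX)
  pg <- proteinToGraph(prot)
  base <- plec(lig@graph, poseCoords(lig), pg, protX)
  theta <- pi / 2
  R <- matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0, 0, 0, 1), 3)
  shift <- c(11, -4, 2)
  moved <- plec(lig@graph, sweep(poseCoords(lig) %*% t(R), 2, shift, "+"),
                pg, sweep(protX %*% t(R), 2, shift, "+"))
  expect_identical(bitIndices(moved), bitIndices(base))

  farFp <- plec(lig@graph, sweep(poseCoords(lig), 2, c(100, 0, 0), "+"), pg, protX)
  expect_length(bitIndices(farFp), 0L)
})

test_that("a single contact pair sets at most one bit per depth combination", {
  lig <- makeChainPose(matrix(c(0, 0, 0), 1), "C")
  prot <- makeShellProtein(matrix(c(3, 0, 0), 1), "N")
  pg <- proteinToGraph(prot)
  fp <- plec(lig@graph, poseCoords(lig), pg, matrix(c(3, 0, 0), 1),
             depthLigand = 2L, depthProtein = 4L)
  expect_lte(length(bitIndices(fp)), 15L)  # (2+1) x (4+1) combinations
  expect_gte(length(bitIndices(fp)), 1L)
})

test_that("adding a contact never clears fingerprint bits", {
  lig <- makeChainPose(matrix(c(0, 0, 0), 1), "C")
  pg1 <- proteinToGraph(makeShellProtein(matrix(c(3, 0, 0), 1), "N"))
  near1 <- plec(lig@graph, poseCoords(lig), pg1, matrix(c(3, 0, 0), 1))
  P2 <- rbind(c(3, 0, 0), c(0, 3, 0))
  pg2 <- proteinToGraph(makeShellProtein(P2, c("N", "O")))
  near2 <- plec(lig@graph, poseCoords(lig), pg2, P2)
  expect_true(all(bitIndices(near1) %in% bitIndices(near2)))
})

test_that("dense expansion and fingerprint union are consistent", {
  f <- ecfp(molGraphFromSmiles("CCO"), nbits = 64L)
  v <- denseVector(f)
  expect_equal(sum(v), length(bitIndices(f)))
  expect_equal(which(v == 1) - 1L, bitIndices(f))
  expect_error(fpUnion(f, ecfp(molGraphFromSmiles("CCO"), nbits = 128L)),
               "widths differ")
})
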