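test_that("docking box construction pads the bounding box on every face", {
  b <- makeBox(rbind(c(0, 0, 0), c(10, 10, 10)), padding = 5)
  expect_equal(b@center, c(5, 5, 5))
  expect_equal(b@extents, c(20, 20, 20))

  b1 <- makeBox(matrix(c(1, 2, 3), nrow = 1), padding = 5)
  expect_equal(b1@center, c(1, 2, 3))
  expect_equal(b1@extents, c(10, 10, 10))

  b0 <- makeBox(rbind(c(0, 0, 0), c(4, 2, 8)), padding = 0)
  expect_error(validObject(b0), NA)
  expect_equal(b0@extents, c(4, 2, 8))

  expect_error(makeBox(matrix(numeric(0), ncol = 3)), "point")
})

test_that("pairwise clash contribution is the linear vdW overlap", {
  expect_equal(clashContribution(3.4, 1.7, 1.7), 0)
  expect_equal(clashContribution(0, 1.7, 1.7), 3.4)
  expect_equal(clashContribution(2.4, 1.7, 1.55), 0.85)
  expect_error(clashContribution(-0.1, 1.7, 1.7), "negative")
  # continuous, non-increasing in d
  d <- seq(0, 5, by = 0.01)
  v <- clashContribution(d, 1.7, 1.55)
  expect_true(all(diff(v) <= 0))
})

test_that("pose clash score equals the all-pairs brute-force oracle", {
  set.seed(7)
  for (rep in 1:25) {
    L <- matrix(rnorm(3 * sample(2:6, 1), sd = 2), ncol = 3)
    P <- matrix(rnorm(3 * sample(3:10, 1), sd = 3), ncol = 3)
    pose <- makeChainPose(L, sample(c("C", "N", "O"), nrow(L), TRUE))
    prot <- makeShellProtein(P, sample(c("C", "N", "O", "S"), nrow(P), TRUE))
    # with an unrestricted selection the 4 A shortcut must be exact
    cs <- poseClashScore(pose, prot, selectionCutoff = Inf)
    expect_equal(cs$total, bruteClash(pose, prot), tolerance = 1e-12)
    expect_equal(cs$total, sum(cs$per_pair$contribution))
    expect_true(all(cs$per_pair$contribution >= 0))
    # the default 4 A selection cannot lose contributions (all radius sums < 4)
    expect_equal(poseClashScore(pose, prot)$total, cs$total, tolerance = 1e-12)
  }
})

test_that("clash score depends only on pairwise distances (rigid-motion invariant)", {
  set.seed(12)
  L <- matrix(rnorm(9), ncol = 3)
  P <- matrix(rnorm(15, sd = 2), ncol = 3)
  pose <- makeChainPose(L); prot <- makeShellProtein(P)
  base <- poseClashScore(pose, prot)$total
  theta <- 1.1
  R <- matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0, 0, 0, 1), 3)
  shift <- c(5, -2, 3)
  pose2 <- makeChainPose(sweep(L %*% t(R), 2, shift, "+"))
  P2 <- sweep(P %*% t(R), 2, shift, "+")
  prot2 <- makeShellProtein(P2)
  expect_equal(poseClashScore(pose2, prot2)$total, base, tolerance = 1e-9)
})

test_that("clash corner cases: separation gives zero, concentric atoms the radius sum", {
  pose <- makeChainPose(matrix(c(0, 0, 0), 1))
  far <- makeShellProtein(matrix(c(10, 0, 0), 1))
  expect_equal(poseClashScore(pose, far)$total, 0)
  conc <- makeShellProtein(matrix(c(0, 0, 0), 1))
  expect_equal(poseClashScore(pose, conc)$total, 3.4)
  expect_error(poseClashScore(pose, makeShellProtein(matrix(numeric(0), ncol = 3))))
})

test_that("threshold calibration returns mu + 3 sigma and filters strictly", {
  set.seed(1)
  draws <- rnorm(10000, mean = 4, sd = 2)
  thr <- fitClashThreshold(draws)
  expect_equal(thr, 10.0, tolerance = 0.15)
  expect_equal(fitClashThreshold(c(3.3, 3.3, 3.3)), 3.3)
  expect_error(fitClashThreshold(5), "at least 2")

  expect_equal(filterPoses(c(2.1, 9.9, 10.0, 14.2), 10), c(2.1, 9.9))
  expect_equal(filterPoses(c(2.1, 9.9, 10.0, 14.2), Inf), c(2.1, 9.9, 10.0, 14.2))
  expect_equal(filterPoses(numeric(0), 10), numeric(0))

  # 3-sigma rule: the fitted threshold retains >= 99% of a single population
  set.seed(2)
  pop <- rnorm(10000, 5, 1.5)
  expect_gte(length(filterPoses(pop, fitClashThreshold(pop))) / length(pop), 0.99)
})

test_that("symmetry-aware RMSD minimises over automorphisms without re-superposition", {
  set.seed(4)
  X <- matrix(rnorm(15), 5)
  a <- makeChainPose(X)
  expect_equal(ligandRmsd(a, a), 0)
  b <- makeChainPose(sweep(X, 2, c(3, 0, 0), "+"))
  expect_equal(ligandRmsd(a, b), 3, tolerance = 1e-12)

  # para-disubstituted ring flipped about its symmetry axis: automorphism
  # matching must report zero
  ringXY <- cbind(cos(seq(0, 5) * pi / 3), sin(seq(0, 5) * pi / 3), 0)
  X1 <- rbind(ringXY, c(2, 0, 0), c(-2, 0, 0))  # ring + 2 para substituents
  el <- c(rep("C", 6), "F", "F")
  bonds <- data.frame(i = c(1, 2, 3, 4, 5, 6, 1, 4), j = c(2, 3, 4, 5, 6, 1, 7, 8),
                      order = 1L)
  p1 <- makeChainPose(X1, el, bonds)
  flip <- diag(c(1, -1, -1))  # 180 degrees about x: maps the ring onto itself
  p2 <- makeChainPose(X1 %*% flip, el, bonds)
  expect_equal(ligandRmsd(p1, p2), 0, tolerance = 1e-9)

  expect_error(ligandRmsd(a, p1), "graphs differ")
})

test_that("ligand RMSD behaves as a pseudo-metric on sampled triples", {
  set.seed(21)
  for (rep in 1:10) {
    X <- matrix(rnorm(18), 6)
    p <- lapply(1:3, function(k) makeChainPose(X + matrix(rnorm(18, sd = 0.5), 6)))
    d12 <- ligandRmsd(p[[1]], p[[2]]); d21 <- ligandRmsd(p[[2]], p[[1]])
    d13 <- ligandRmsd(p[[1]], p[[3]]); d23 <- ligandRmsd(p[[2]], p[[3]])
    expect_equal(d12, d21, tolerance = 1e-12)
    expect_lte(d13, d12 + d23 + 1e-12)
  }
})

test_that("MOL round-trip preserves elements, bonds and coordinates to format precision", {
  set.seed(9)
  X <- matrix(round(rnorm(12, sd = 3), 4), 4)
  pose <- makeChainPose(X, c("C", "N", "O", "C"))
  txt <- writePoseMol(pose)
  back <- readPoseMol(txt)
  expect_equal(atoms(back)$element, atoms(pose)$element)
  expect_equal(bonds(back), bonds(pose))
  expect_lt(max(abs(poseCoords(back) - poseCoords(pose))), 1e-3)

  # single-atom block
  p1 <- makeChainPose(matrix(c(1.5, -2.25, 0.125), 1), "C")
  b1 <- readPoseMol(writePoseMol(p1))
  expect_equal(nrow(atoms(b1)), 1L)
  expect_lt(max(abs(poseCoords(b1) - poseCoords(p1))), 1e-3)
})

test_that("malformed structure files fail with a line number", {
  expect_error(readPoseMol(c("t", "", "", "bad counts")), "line 4")
  pose <- makeChainPose(matrix(rnorm(9), 3))
  lines <- strsplit(writePoseMol(pose), "\n")[[1]]
  lines[5] <- "garbage atom line"
  expect_error(readPoseMol(lines), "line 5")

  tc <- makeToyComplex(seed = 2)
  ptxt <- writeProteinPdb(tc$protein)
  plines <- strsplit(ptxt, "\n")[[1]]
  plines[3] <- "ATOM      3  X"
  expect_error(readProteinPdb(text = plines), "line 3")
})

test_that("PDB read keeps ATOM records and matches the written structure", {
  tc <- makeToyComplex(seed = 5, nProteinAtoms = 24)
  txt <- writeProteinPdb(tc$protein)
  back <- readProteinPdb(text = txt, structureId = "rt")
  expect_equal(nrow(atoms(back)), 24L)
  expect_equal(atoms(back)$element, atoms(tc$protein)$element)
  expect_lt(max(abs(as.matrix(atoms(back)[, c("x", "y", "z")]) -
                    as.matrix(atoms(tc$protein)[, c("x", "y", "z")]))), 1e-3)
  # HETATM lines are not protein atoms unless requested
  het <- c(strsplit(txt, "\n")[[1]][1:3],
           "HETATM   99  C1  LIG A 999      0.000   0.000   0.000  1.00  0.00           C",
           "END")
  expect_equal(nrow(atoms(readProteinPdb(text = het))), 3L)
  expect_equal(nrow(atoms(readProteinPdb(text = het, includeHet = TRUE))), 4L)
})
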