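test_that("toy complexes hit the clash target and are deterministic", {
  tc0 <- makeToyComplex(seed = 3, targetClash = 0)
  expect_equal(tc0$pose@clashScore, 0)
  expect_equal(poseClashScore(tc0$pose, tc0$protein)$total, 0)

  tc5 <- makeToyComplex(seed = 11, targetClash = 5.0)
  oracle <- bruteClash(tc5$pose, tc5$protein)
  expect_gte(oracle, 4.5); expect_lte(oracle, 5.5)

  a <- makeToyComplex(seed = 17, targetClash = 2.0)
  b <- makeToyComplex(seed = 17, targetClash = 2.0)
  expect_identical(poseCoords(a$pose), poseCoords(b$pose))
  expect_identical(atoms(a$protein), atoms(b$protein))

  expect_error(makeToyComplex(seed = 1, nProteinAtoms = 4, nLigandAtoms = 1,
                              targetClash = 500), "unreachable")
  # generated objects satisfy their class invariants
  expect_true(validObject(a$pose))
  expect_true(validObject(a$protein))
})

test_that("planted SAR is exactly linear without noise and seed-reproducible", {
  ps <- plantSar(seed = 5, nSamples = 600, nbits = 64, noiseSd = 0)
  fit <- stats::lm.fit(cbind(1, ps$X), ps$y)
  expect_lt(max(abs(fit$coefficients[-1] - ps$w)), 1e-6)
  expect_lt(abs(fit$coefficients[1]), 1e-6)

  again <- plantSar(seed = 5, nSamples = 600, nbits = 64, noiseSd = 0)
  expect_identical(ps, again)
  different <- plantSar(seed = 6, nSamples = 600, nbits = 64, noiseSd = 0)
  expect_false(identical(ps$w, different$w))
})

test_that("ridge regression reaches the analytic noise ceiling on planted SAR", {
  skip_if_not_installed("glmnet")
  sar <- plantSar(seed = 1, nSamples = 6250, nbits = 256, bitDensity = 0.05,
                  weightScale = 0.3, noiseSd = 0.3)
  tr <- 1:5000
  v <- stats::var(as.numeric(sar$X %*% sar$w))
  ceil <- v / (v + 0.09)
  fit <- glmnet::glmnet(sar$X[tr, ], sar$y[tr], alpha = 0, lambda = 0.05)
  pred <- as.numeric(glmnet::predict.glmnet(fit, sar$X[-tr, ]))
  expect_equal(rSquared(pred, sar$y[-tr]), ceil, tolerance = 0.05)
})

test_that("toy benchmark plants exactly the advertised defect counts", {
  tb <- makeToyBenchmark(seed = 2, nKinases = 3, nStructuresPerKinase = 2,
                         nCompounds = 100, activitiesPerCompound = 2,
                         fracMwViolations = 0.1)
  fails <- !filterCompound(tb$compounds)
  expect_equal(sum(fails, na.rm = TRUE), 10L)
  expect_equal(tb$expected$failing_compounds, 10L)
  expect_equal(sum(tb$activities$is_mutant), tb$expected$mutant_records)
  sel <- selectStructures(tb$structures)
  expect_equal(nrow(sel), tb$expected$surviving_structures)

  # group labels cycle over at most three groups
  expect_lte(length(unique(tb$structures$kinase_group)), 3L)

  again <- makeToyBenchmark(seed = 2, nKinases = 3, nStructuresPerKinase = 2,
                            nCompounds = 100, activitiesPerCompound = 2,
                            fracMwViolations = 0.1)
  expect_identical(tb$compounds, again$compounds)
  expect_identical(tb$structures$pdb_text, again$structures$pdb_text)
})

test_that("benchmark fixtures pass through the real parsers", {
  tb <- makeToyBenchmark(seed = 13, nKinases = 2, nStructuresPerKinase = 1,
                         nCompounds = 6, fracBadResolution = 0)
  for (k in seq_len(nrow(tb$structures))) {
    ps <- readProteinPdb(text = tb$structures$pdb_text[k])
    expect_s4_class(ps, "ProteinStructure")
    expect_gt(nrow(atoms(ps)), 0L)
  }
  for (smi in tb$compounds$smiles)
    expect_s4_class(molGraphFromSmiles(smi), "MolGraph")
})
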