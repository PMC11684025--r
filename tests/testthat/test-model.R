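test_that("R-squared follows the squared-Pearson convention", {
  obs <- c(1, 2, 3)
  expect_equal(rSquared(obs, obs), 1.0)
  expect_equal(rSquared(2 * obs + 1, obs), 1.0)  # affine invariance
  expect_equal(rSquared(c(1, 2, 4), obs), 0.9643, tolerance = 1e-4)
  expect_error(rSquared(c(1, 2), c(5, 5)), "constant")
  expect_error(rSquared(1:3, 1:4), "length")
  # coefficient-of-determination variant penalises systematic offset
  expect_lt(rSquared(2 * obs + 1, obs, method = "cod"), 1.0)
})

test_that("KS statistic matches stats::ks.test on tie-free samples", {
  set.seed(5)
  x <- rnorm(40); y <- rnorm(60, 0.3)
  expect_equal(ksStatistic(x, y),
               unname(suppressWarnings(stats::ks.test(x, y)$statistic)))
})

makeActs <- function(n, nComp, nKin, seed) {
  set.seed(seed)
  data.frame(
    activity_id = sprintf("A%04d", seq_len(n)),
    compound_id = sprintf("C%03d", 1L + (seq_len(n) - 1L) %% nComp),
    accession = sprintf("K%02d", 1L + (seq_len(n) - 1L) %% nKin),
    pchembl = rnorm(n, 6.5, 1))
}

test_that("splits are sized 80:20, entity-disjoint and seed-deterministic", {
  acts <- makeActs(100, 20, 10, 1)
  s <- makeSplits(acts, "random", seed = 42)
  expect_length(s@testIds, 20L)
  expect_length(intersect(s@trainIds, s@testIds), 0L)

  compOf <- function(ids) unique(acts$compound_id[match(ids, acts$activity_id)])
  kinOf <- function(ids) unique(acts$accession[match(ids, acts$activity_id)])

  sc <- makeSplits(acts, "compound", seed = 42)
  expect_length(intersect(compOf(sc@trainIds), compOf(sc@testIds)), 0L)

  sk <- makeSplits(acts, "kinase", seed = 42)
  expect_length(kinOf(sk@testIds), 2L)  # 2 of 10 kinases wholly in test
  expect_length(intersect(kinOf(sk@trainIds), kinOf(sk@testIds)), 0L)

  expect_identical(makeSplits(acts, "compound", seed = 42)@testIds, sc@testIds)
  expect_false(identical(makeSplits(acts, "compound", seed = 43)@testIds,
                         sc@testIds))

  one <- data.frame(compound_id = "C1", accession = sprintf("K%d", 1:6),
                    pchembl = rnorm(6))
  expect_error(makeSplits(one, "compound"), "one distinct entity")
})

test_that("returned split beats the median rejected candidate on KS distance", {
  for (seed in c(3, 14, 15)) {
    acts <- makeActs(150, 30, 6, seed)
    for (strat in c("random", "compound", "kinase")) {
      s <- makeSplits(acts, strat, seed = seed)
      expect_lte(s@ks, stats::median(s@candidateKs))
      expect_equal(min(s@candidateKs), s@ks)
    }
  }
})

test_that("training converges on planted SAR data and keeps the best checkpoint", {
  sar <- plantSar(seed = 2, nSamples = 1200, nbits = 64, bitDensity = 0.1,
                  weightScale = 0.4, noiseSd = 0.3)
  tr <- 1:900
  spec <- scoringNetworkSpec(64, 64, 16)
  cfg <- trainingConfig(learningRate = 2e-3, batchSize = 128, epochs = 40, seed = 5)
  mod <- trainScoringNetwork(spec, sar$X[tr, ], sar$y[tr],
                             sar$X[-tr, ], sar$y[-tr], cfg)
  expect_true(all(is.finite(mod@history$train_loss)))
  expect_equal(nrow(mod@history), 40L)
  # best-checkpoint bookkeeping: returned model reproduces the best metric
  best <- max(mod@history$test_metric)
  expect_equal(mod@history$test_metric[mod@bestEpoch], best)
  expect_equal(rSquared(predictAffinity(mod, sar$X[-tr, ]), sar$y[-tr]), best,
               tolerance = 1e-9)
  expect_gte(best, mod@history$test_metric[nrow(mod@history)])
  expect_gte(best, 0.5)
})

test_that("zero-epoch training returns the initial model with empty history", {
  sar <- plantSar(seed = 3, nSamples = 50, nbits = 32)
  spec <- scoringNetworkSpec(32, 8, 4)
  mod <- trainScoringNetwork(spec, sar$X[1:40, ], sar$y[1:40],
                             sar$X[41:50, ], sar$y[41:50],
                             trainingConfig(epochs = 0, seed = 1))
  expect_equal(nrow(mod@history), 0L)
  expect_equal(mod@bestEpoch, 0L)
  expect_true(all(is.finite(predictAffinity(mod, sar$X[41:50, ]))))
})

test_that("prediction is deterministic, batch-invariant and width-checked", {
  sar <- plantSar(seed = 4, nSamples = 60, nbits = 32)
  spec <- scoringNetworkSpec(32, 8, 4)
  mod <- trainScoringNetwork(spec, sar$X[1:50, ], sar$y[1:50],
                             sar$X[51:60, ], sar$y[51:60],
                             trainingConfig(learningRate = 1e-3, epochs = 3,
                                            batchSize = 16, seed = 2))
  X <- sar$X[51:60, ]
  expect_identical(predictAffinity(mod, X), predictAffinity(mod, X))
  single <- vapply(seq_len(nrow(X)), function(i)
    predictAffinity(mod, X[i, ]), numeric(1))
  expect_equal(predictAffinity(mod, X), single, tolerance = 1e-12)
  # all-zero fingerprint flows through the bias pathway only
  expect_true(is.finite(predictAffinity(mod, numeric(32))))
  expect_error(predictAffinity(mod, numeric(33)), "width")
  expect_error(trainScoringNetwork(spec, sar$X[1:50, 1:30], sar$y[1:50],
                                   sar$X[51:60, ], sar$y[51:60]), "width")
})

test_that("network archives round-trip through the text serialisation", {
  sar <- plantSar(seed = 6, nSamples = 40, nbits = 16)
  mod <- trainScoringNetwork(scoringNetworkSpec(16, 6, 3),
                             sar$X[1:30, ], sar$y[1:30], sar$X[31:40, ],
                             sar$y[31:40],
                             trainingConfig(epochs = 2, batchSize = 8, seed = 3))
  f <- tempfile(fileext = ".txt")
  writeScoringNetwork(mod, f)
  back <- readScoringNetwork(f)
  expect_equal(predictAffinity(back, sar$X[31:40, ]),
               predictAffinity(mod, sar$X[31:40, ]), tolerance = 1e-12)
  expect_equal(back@history$test_metric, mod@history$test_metric)
})

test_that("per-kinase metrics roll up into unweighted group means", {
  pr <- data.frame(
    accession = c("K1", "K1", "K1", "K2", "K2", "K3"),
    kinase_group = c("TK", "TK", "TK", "TK", "TK", "CMGC"),
    obs = c(5, 6, 7, 5, 7, 6),
    pred = c(5.1, 5.9, 7.2, 7, 5, 9))
  m <- perKinaseMetrics(pr)
  expect_equal(nrow(m$perKinase), 3L)
  # K3 has a single point: flagged, excluded from the group mean
  expect_false(m$perKinase$defined[m$perKinase$accession == "K3"])
  expect_true(is.na(m$perGroup$mean_r_squared[m$perGroup$kinase_group == "CMGC"]))
  r1 <- m$perKinase$r_squared[m$perKinase$accession == "K1"]
  r2 <- m$perKinase$r_squared[m$perKinase$accession == "K2"]
  expect_equal(m$perGroup$mean_r_squared[m$perGroup$kinase_group == "TK"],
               mean(c(r1, r2)))
  # single defined kinase in a group: group mean equals that kinase's value
  pr2 <- pr[pr$accession == "K1", ]
  m2 <- perKinaseMetrics(pr2)
  expect_equal(m2$perGroup$mean_r_squared, r1)
})

test_that("per-kinase training respects the unique-inhibitor threshold", {
  set.seed(8)
  nA <- 30; nB <- 8
  acts <- data.frame(
    compound_id = c(sprintf("A%03d", 1:nA), sprintf("B%03d", 1:nB)),
    accession = c(rep("K1", nA), rep("K2", nB)),
    pchembl = rnorm(nA + nB, 6.5, 1))
  fps <- lapply(seq_len(nA + nB), function(i) {
    new("Fingerprint", nbits = 32L,
        bits = sort(sample(0:31, 4)))
  })
  names(fps) <- acts$compound_id
  res <- trainPerKinase(acts, fps, minInhibitors = 20L,
                        spec = scoringNetworkSpec(32, 8, 4),
                        config = trainingConfig(learningRate = 1e-3,
                                                epochs = 2, batchSize = 8,
                                                seed = 4))
  expect_equal(names(res$models), "K1")
  expect_equal(res$skipped$accession, "K2")
  expect_equal(res$skipped$n_compounds, nB)
  # trained + skipped partition all kinases
  expect_setequal(c(names(res$models), res$skipped$accession),
                  unique(acts$accession))
  # threshold 0 trains a model for every kinase
  res0 <- trainPerKinase(acts, fps, minInhibitors = 0L,
                         spec = scoringNetworkSpec(32, 8, 4),
                         config = trainingConfig(learningRate = 1e-3,
                                                 epochs = 2, batchSize = 8,
                                                 seed = 4))
  expect_setequal(names(res0$models), c("K1", "K2"))
})
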