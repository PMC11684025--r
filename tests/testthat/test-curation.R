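test_that("drug-likeness filter applies inclusive bounds and flags missing descriptors", {
  rules <- druglikenessRules()
  cases <- data.frame(
    mw   = c(500.0, 249.9, 750.0, 250.0, 500, 500, 500, NA),
    hbd  = c(2,     2,     10,    0,     11,  2,   2,   2),
    hba  = c(5,     5,     15,    0,     5,   16,  5,   5),
    rotb = c(8,     8,     15,    0,     8,   8,   16,  8))
  expect_identical(filterCompound(cases, rules),
                   c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, NA))
})

test_that("relaxing any rule bound never decreases the surviving compound count", {
  set.seed(31)
  comp <- data.frame(mw = runif(200, 100, 900), hbd = sample(0:14, 200, TRUE),
                     hba = sample(0:20, 200, TRUE), rotb = sample(0:20, 200, TRUE))
  base <- sum(filterCompound(comp, druglikenessRules()), na.rm = TRUE)
  relaxed <- list(druglikenessRules(mwMin = 150), druglikenessRules(mwMax = 900),
                  druglikenessRules(hbdMax = 14), druglikenessRules(hbaMax = 25),
                  druglikenessRules(rotbMax = 25))
  for (r in relaxed)
    expect_gte(sum(filterCompound(comp, r), na.rm = TRUE), base)
})

test_that("activity aggregation removes mutants and pools activity types by plain mean", {
  recs <- data.frame(
    compound_id = c("C1", "C1", "C1", "C2"),
    accession = c("K1", "K1", "K2", "K1"),
    pchembl = c(6.0, 7.0, 5.0, 8.0),
    activity_type = c("pIC50", "pKi", "pKd", "pKd"),
    is_mutant = c(FALSE, FALSE, FALSE, FALSE))
  agg <- aggregateActivities(recs)
  expect_equal(agg$pchembl[agg$compound_id == "C1" & agg$accession == "K1"], 6.5)
  expect_equal(agg$pchembl[agg$compound_id == "C1" & agg$accession == "K2"], 5.0)
  expect_equal(nrow(agg), 3L)

  onlyMutant <- data.frame(compound_id = "C1", accession = "K1", pchembl = 6.0,
                           activity_type = "pIC50", is_mutant = TRUE)
  expect_equal(nrow(aggregateActivities(onlyMutant)), 0L)
  expect_equal(nrow(aggregateActivities(recs[0, ])), 0L)
})

makeStructs <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(structure_id = r[[1]], accession = r[[2]], resolution = r[[3]],
               quality_score = r[[4]], missing_residues = r[[5]],
               dfg_state = r[[6]], ac_helix_state = r[[7]],
               stringsAsFactors = FALSE)))
}

test_that("structure selection enforces quality gates and keeps the best per state", {
  s <- makeStructs(
    list("S1", "K1", 2.6, 9, 0, "in", "in"),     # fails resolution
    list("S2", "K1", 2.0, 9, 0, "in", "in"),
    list("S3", "K1", 2.0, 10, 0, "in", "in"),    # beats S2 on quality
    list("S4", "K1", 2.0, 9, 6, "out", "in"),    # fails missing residues
    list("S5", "K1", 2.0, 7, 0, "out", "out"),   # fails quality
    list("S6", "K1", 1.8, 9, 2, "out", "out"),
    list("S7", "K1", 2.2, 9, 1, "out-like", "out"))  # folded into out; loses to S6? no: quality tie
  sel <- selectStructures(s)
  expect_false("S1" %in% sel$structure_id)
  expect_true("S3" %in% sel$structure_id)
  expect_false("S2" %in% sel$structure_id)
  # S6 and S7 tie on quality 9 in the (out, out) cell; lower resolution wins
  expect_true("S6" %in% sel$structure_id)
  expect_false("S7" %in% sel$structure_id)
  expect_false(any(c("S4", "S5") %in% sel$structure_id))
})

test_that("one survivor per state combination gives at most four per kinase", {
  s <- makeStructs(
    list("A1", "K1", 2.0, 9, 0, "in", "in"),
    list("A2", "K1", 2.0, 9, 0, "in", "out"),
    list("A3", "K1", 2.0, 9, 0, "out", "in"),
    list("A4", "K1", 2.0, 9, 0, "out", "out"))
  expect_equal(sort(selectStructures(s)$structure_id), c("A1", "A2", "A3", "A4"))

  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    rnd <- data.frame(
      structure_id = sprintf("R%02d", seq_len(n)),
      accession = sample(c("K1", "K2", "K3"), n, TRUE),
      resolution = runif(n, 1.5, 3.0),
      quality_score = runif(n, 6, 10),
      missing_residues = sample(0:8, n, TRUE),
      dfg_state = sample(c("in", "out", "out-like"), n, TRUE),
      ac_helix_state = sample(c("in", "out"), n, TRUE),
      stringsAsFactors = FALSE)
    sel <- selectStructures(rnd)
    if (nrow(sel))
      expect_true(all(table(sel$accession) <= 4L))
  }
})

test_that("dataset assembly composes the three filters and enforces referential rules", {
  comps <- data.frame(
    compound_id = c("C1", "C2", "C3"),
    smiles = c("CCO", "CCC", "CCCC"),
    mw = c(400, 200, 500), hbd = c(1, 1, 1), hba = c(2, 2, 2),
    rotb = c(3, 3, 3), stringsAsFactors = FALSE)  # C2 fails MW
  acts <- data.frame(
    compound_id = c("C1", "C1", "C2", "C3"),
    accession = c("K1", "K1", "K1", "K2"),
    pchembl = c(6, 7, 5, 8),
    activity_type = "pIC50",
    is_mutant = c(FALSE, TRUE, FALSE, FALSE), stringsAsFactors = FALSE)
  structs <- data.frame(
    structure_id = c("S1", "S2"), accession = c("K1", "K2"),
    resolution = c(2.0, 2.6),  # S2 fails
    quality_score = c(9, 9), missing_residues = c(0, 0),
    dfg_state = "in", ac_helix_state = "in", stringsAsFactors = FALSE)
  ds <- buildDataset(acts, comps, structs)
  expect_equal(sort(compounds(ds)$compound_id), c("C1", "C3"))
  # C3's kinase K2 lost its only structure, so only C1-K1 survives
  expect_equal(nrow(activities(ds)), 1L)
  expect_equal(activities(ds)$pchembl, 6.0)  # mutant record removed before mean
  expect_equal(structures(ds)$structure_id, "S1")

  empty <- buildDataset(acts[0, ], comps[0, ], structs[0, ])
  expect_equal(nrow(compounds(empty)), 0L)
  expect_equal(nrow(activities(empty)), 0L)

  compsDup <- rbind(comps, data.frame(compound_id = "C1", smiles = "CCN",
                                      mw = 400, hbd = 1, hba = 2, rotb = 3))
  expect_error(buildDataset(acts, compsDup, structs), "C1")
})

test_that("curation is idempotent on its own re-exported output", {
  tb <- makeToyBenchmark(seed = 8)
  ds1 <- buildDataset(tb$activities, tb$compounds, tb$structures)
  raw <- exportTables(ds1)
  ds2 <- buildDataset(raw$activities, raw$compounds, raw$structures)
  expect_equal(compounds(ds2), compounds(ds1))
  expect_equal(activities(ds2), activities(ds1))
  expect_equal(structures(ds2)$structure_id, structures(ds1)$structure_id)
})
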