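# Leakage-aware dataset splitting and evaluation metrics.

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Maximum absolute difference between the empirical distribution functions
#' of two samples (ties handled exactly; no p-value).
#'
#' @param x,y numeric samples.
#' @return the KS statistic D.
#' @export
ksStatistic <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample")
  pts <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(pts)
  Fy <- stats::ecdf(y)(pts)
  max(abs(Fx - Fy))
}

# one candidate partition; returns list(train, test) of activity ids
.drawPartition <- function(ids, entity, strategy, testFraction) {
  n <- length(ids)
  target <- testFraction * n
  if (strategy == "random") {
    k <- round(target)
    testIdx <- sample.int(n, k)
  } else {
    ents <- unique(entity)
    if (length(ents) < 2L)
      stop("entity split impossible: only one distinct entity")
    perm <- sample(ents)
    cnt <- 0L; chosen <- character(0)
    for (e in perm) {
      ne <- sum(entity == e)
      # add the entity only while it brings the test count closer to target
      if (abs(cnt + ne - target) <= abs(cnt - target)) {
        chosen <- c(chosen, e); cnt <- cnt + ne
      }
      if (cnt >= target) break
    }
    if (!length(chosen)) chosen <- perm[1]
    if (length(chosen) == length(ents)) chosen <- chosen[-length(chosen)]
    testIdx <- which(entity %in% chosen)
  }
  list(train = ids[-testIdx], test = ids[testIdx])
}

#' Leakage-aware train/test split
#'
#' 80:20 partition of activity records, by record (`random`) or by whole
#' entity (`compound`: completely unseen compounds in the test set;
#' `kinase`: completely unseen kinases). Splits are curated for
#' distributional similarity: among `attempts` seeded candidate partitions
#' the one with the smallest Kolmogorov-Smirnov statistic between the train
#' and test pChEMBL distributions is returned. Deterministic given `seed`.
#'
#' @param acts data.frame with columns `compound_id`, `accession`,
#'   `pchembl`, and optionally `activity_id` (generated when absent).
#' @param strategy "random", "compound" or "kinase".
#' @param testFraction target test fraction (default 0.2).
#' @param seed integer seed.
#' @param attempts number of candidate partitions considered (default 25).
#' @return a [SplitAssignment-class].
#' @export
makeSplits <- function(acts, strategy = c("random", "compound", "kinase"),
                       testFraction = 0.2, seed = 1L, attempts = 25L) {
  strategy <- match.arg(strategy)
  if (nrow(acts) < 5L) stop("at least 5 records required")
  if (!"activity_id" %in% names(acts))
    acts$activity_id <- sprintf("rec%06d", seq_len(nrow(acts)))
  ids <- as.character(acts$activity_id)
  if (anyDuplicated(ids)) stop("activity_id values must be unique")
  entity <- switch(strategy, random = ids,
                   compound = as.character(acts$compound_id),
                   kinase = as.character(acts$accession))
  if (strategy != "random" && length(unique(entity)) < 2L)
    stop("entity split impossible: only one distinct entity")
  pch <- acts$pchembl
  names(pch) <- ids
  .withSeed(seed, {
    best <- NULL; bestKs <- Inf; ksAll <- numeric(attempts)
    for (a in seq_len(attempts)) {
      part <- .drawPartition(ids, entity, strategy, testFraction)
      ksAll[a] <- ksStatistic(pch[part$train], pch[part$test])
      if (ksAll[a] < bestKs) { bestKs <- ksAll[a]; best <- part }
    }
    new("SplitAssignment", strategy = strategy, trainIds = best$train,
        testIds = best$test, testFraction = testFraction, ks = bestKs,
        candidateKs = ksAll)
  })
}

#' Per-kinase and per-group performance metrics
#'
#' One R2 row per kinase with at least two test points; kinases with fewer
#' are flagged undefined and excluded from group means. The group rollup is
#' the unweighted mean of the member kinases' R2.
#'
#' @param predictions data.frame with columns `accession`, `kinase_group`,
#'   `pred`, `obs`.
#' @return list with `perKinase` (accession, kinase_group, n_test,
#'   r_squared, defined) and `perGroup` (kinase_group, n_kinases,
#'   mean_r_squared).
#' @export
perKinaseMetrics <- function(predictions) {
  stopifnot(all(c("accession", "kinase_group", "pred", "obs") %in%
                names(predictions)))
  accs <- unique(predictions$accession)
  rows <- lapply(accs, function(a) {
    d <- predictions[predictions$accession == a, , drop = FALSE]
    defined <- nrow(d) >= 2L && stats::sd(d$obs) > 0
    data.frame(accession = a, kinase_group = d$kinase_group[1],
               n_test = nrow(d),
               r_squared = if (defined) rSquared(d$pred, d$obs) else NA_real_,
               defined = defined)
  })
  perKinase <- do.call(rbind, rows)
  def <- perKinase[perKinase$defined, , drop = FALSE]
  groups <- unique(perKinase$kinase_group)
  perGroup <- do.call(rbind, lapply(groups, function(g) {
    d <- def[def$kinase_group == g, , drop = FALSE]
    data.frame(kinase_group = g, n_kinases = nrow(d),
               mean_r_squared = if (nrow(d)) mean(d$r_squared) else NA_real_)
  }))
  list(perKinase = perKinase, perGroup = perGroup)
}

#' Train one ECFP model per kinase
#'
#' For every kinase with at least `minInhibitors` unique compounds, trains
#' a separate scoring network on the compounds' ECFP fingerprints (the
#' published per-kinase models used a 100-inhibitor minimum with 2048-bit
#' ECFP4 input); kinases below the threshold are reported as skipped.
#'
#' @param acts data.frame (compound_id, accession, pchembl).
#' @param fingerprints named list of [Fingerprint-class], one per
#'   compound_id.
#' @param minInhibitors unique-compound threshold (default 100).
#' @param spec a [scoringNetworkSpec()] (input width must match the
#'   fingerprints).
#' @param config a [trainingConfig()].
#' @param testFraction held-out fraction per kinase (default 0.2).
#' @return list with `models` (named list of [ScoringNetwork-class]) and
#'   `skipped` (data.frame accession, n_compounds).
#' @export
trainPerKinase <- function(acts, fingerprints, minInhibitors = 100L,
                           spec = scoringNetworkSpec(2048L),
                           config = trainingConfig(), testFraction = 0.2) {
  accs <- unique(acts$accession)
  models <- list(); skipped <- list()
  for (a in accs) {
    d <- acts[acts$accession == a, , drop = FALSE]
    nComp <- length(unique(d$compound_id))
    if (nComp < minInhibitors) {
      skipped[[length(skipped) + 1L]] <- data.frame(accession = a,
                                                    n_compounds = nComp)
      next
    }
    X <- t(vapply(d$compound_id,
                  function(cid) denseVector(fingerprints[[cid]]),
                  numeric(spec$inputBits)))
    d$activity_id <- sprintf("rec%06d", seq_len(nrow(d)))
    split <- makeSplits(d, "random", testFraction,
                        seed = config$seed + .fnv1a32(a) %% 1000L)
    ids <- d$activity_id
    tr <- ids %in% split@trainIds
    models[[a]] <- trainScoringNetwork(spec, X[tr, , drop = FALSE],
                                       d$pchembl[tr], X[!tr, , drop = FALSE],
                                       d$pchembl[!tr], config)
  }
  list(models = models,
       skipped = if (length(skipped)) do.call(rbind, skipped)
                 else data.frame(accession = character(),
                                 n_compounds = integer()))
}
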