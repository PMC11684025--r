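# The 3-layer neural scoring function.
#
# Architecture: input -> hidden1 -> hidden2 -> 1, ReLU after the first two
# layers, linear output; dropout (training only, inverted scaling) on the
# input vector and both hidden activations. Trained with Adam on mean
# squared error at a fixed learning rate; after every epoch the test-set
# metric is evaluated and the best checkpoint is the returned model. The
# published configuration is 4000/1000 hidden units, dropout 0.25, learning
# rate 1e-5, batch size 128, 100 epochs.

#' Network architecture specification
#'
#' @param inputBits fingerprint width (2048 for ECFP, 65536 for PLEC).
#' @param hidden1,hidden2 hidden-layer widths (published model: 4000, 1000).
#' @param dropout dropout rate on input and hidden layers during training.
#' @return list used by [trainScoringNetwork()].
#' @export
scoringNetworkSpec <- function(inputBits, hidden1 = 4000L, hidden2 = 1000L,
                               dropout = 0.25) {
  stopifnot(inputBits >= 1, hidden1 >= 1, hidden2 >= 1,
            dropout >= 0, dropout < 1)
  list(inputBits = as.integer(inputBits),
       hidden = c(as.integer(hidden1), as.integer(hidden2)),
       dropout = dropout)
}

#' Training configuration
#'
#' @param learningRate fixed Adam learning rate (published value 1e-5).
#' @param batchSize minibatch size (default 128).
#' @param epochs number of epochs (default 100; training always runs to
#'   this fixed termination, the best checkpoint is returned).
#' @param seed RNG seed for initialisation, shuffling and dropout masks.
#' @return list used by [trainScoringNetwork()].
#' @export
trainingConfig <- function(learningRate = 1e-5, batchSize = 128L,
                           epochs = 100L, seed = 1L) {
  stopifnot(epochs >= 0, batchSize >= 1, learningRate > 0)
  list(learningRate = learningRate, batchSize = as.integer(batchSize),
       epochs = as.integer(epochs), seed = as.integer(seed))
}

# uniform fan-in initialisation (U(-1/sqrt(fan_in), 1/sqrt(fan_in)))
.initWeights <- function(spec) {
  dims <- c(spec$inputBits, spec$hidden, 1L)
  w <- list()
  for (l in 1:3) {
    fi <- dims[l]
    lim <- 1 / sqrt(fi)
    w[[paste0("W", l)]] <- matrix(stats::runif(fi * dims[l + 1L], -lim, lim),
                                  nrow = fi)
    w[[paste0("b", l)]] <- stats::runif(dims[l + 1L], -lim, lim)
  }
  w
}

.forward <- function(w, X) {
  h1 <- X %*% w$W1
  h1 <- sweep(h1, 2, w$b1, "+"); h1[h1 < 0] <- 0
  h2 <- h1 %*% w$W2
  h2 <- sweep(h2, 2, w$b2, "+"); h2[h2 < 0] <- 0
  out <- h2 %*% w$W3 + w$b3[1]
  list(h1 = h1, h2 = h2, out = as.numeric(out))
}

#' Squared-correlation metric
#'
#' Squared Pearson correlation between predicted and observed values (the
#' scoring-function convention for R2); the coefficient of determination is
#' available via `method = "cod"`.
#'
#' @param pred,obs numeric vectors of equal length >= 2.
#' @param method "pearson" (default) or "cod".
#' @return R2 (in `[0, 1]` for "pearson"; "cod" can be negative).
#' @export
rSquared <- function(pred, obs, method = c("pearson", "cod")) {
  method <- match.arg(method)
  if (length(pred) != length(obs)) stop("length mismatch")
  if (length(obs) < 2L) stop("need at least 2 observations")
  if (stats::sd(obs) == 0) stop("R-squared undefined: observed values are constant")
  if (method == "pearson") {
    if (stats::sd(pred) == 0) return(0)
    stats::cor(pred, obs)^2
  } else {
    1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  }
}

#' Train the scoring network
#'
#' Minibatch Adam on mean squared error for a fixed number of epochs; after
#' every epoch the test-set R2 is recorded and the returned model is the
#' checkpoint with the best test metric, not the final epoch.
#'
#' @param spec a [scoringNetworkSpec()].
#' @param xTrain,xTest numeric matrices (rows = samples, columns =
#'   `spec$inputBits` fingerprint bits).
#' @param yTrain,yTest pChEMBL labels.
#' @param config a [trainingConfig()].
#' @return a [ScoringNetwork-class] (best checkpoint, with full history).
#' @export
trainScoringNetwork <- function(spec, xTrain, yTrain, xTest, yTest,
                                config = trainingConfig()) {
  if (ncol(xTrain) != spec$inputBits || ncol(xTest) != spec$inputBits)
    .stopf("feature width %d does not match spec inputBits %d",
           ncol(xTrain), spec$inputBits)
  n <- nrow(xTrain)
  .withSeed(config$seed, {
    w <- .initWeights(spec)
    best <- w; bestMetric <- -Inf; bestEpoch <- 0L
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       test_metric = numeric())
    # Adam state
    m <- lapply(w, function(p) p * 0); v <- m
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
    p <- spec$dropout
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config$batchSize)
      epochLoss <- 0
      for (s in starts) {
        idx <- perm[s:min(s + config$batchSize - 1L, n)]
        X <- xTrain[idx, , drop = FALSE]
        y <- yTrain[idx]
        nb <- length(idx)
        # forward with inverted dropout on input and hidden activations
        if (p > 0) {
          mIn <- matrix(stats::rbinom(length(X), 1, 1 - p), nrow = nb) / (1 - p)
          X <- X * mIn
        }
        a1 <- sweep(X %*% w$W1, 2, w$b1, "+")
        h1 <- a1; h1[h1 < 0] <- 0
        if (p > 0) {
          m1 <- matrix(stats::rbinom(length(h1), 1, 1 - p), nrow = nb) / (1 - p)
          h1 <- h1 * m1
        }
        a2 <- sweep(h1 %*% w$W2, 2, w$b2, "+")
        h2 <- a2; h2[h2 < 0] <- 0
        if (p > 0) {
          m2 <- matrix(stats::rbinom(length(h2), 1, 1 - p), nrow = nb) / (1 - p)
          h2 <- h2 * m2
        }
        pred <- as.numeric(h2 %*% w$W3 + w$b3[1])
        err <- pred - y
        loss <- mean(err^2)
        if (!is.finite(loss))
          .stopf("training aborted: non-finite loss at epoch %d", epoch)
        epochLoss <- epochLoss + loss * nb
        # backward (MSE: dL/dpred = 2 err / nb)
        dOut <- matrix(2 * err / nb, ncol = 1)
        gW3 <- t(h2) %*% dOut; gb3 <- sum(dOut)
        dH2 <- dOut %*% t(w$W3)
        if (p > 0) dH2 <- dH2 * m2
        dH2[a2 <= 0] <- 0
        gW2 <- t(h1) %*% dH2; gb2 <- colSums(dH2)
        dH1 <- dH2 %*% t(w$W2)
        if (p > 0) dH1 <- dH1 * m1
        dH1[a1 <= 0] <- 0
        gW1 <- t(X) %*% dH1; gb1 <- colSums(dH1)
        g <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
        t <- t + 1
        for (nm in names(w)) {
          m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g[[nm]]
          v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g[[nm]]^2
          mh <- m[[nm]] / (1 - b1^t)
          vh <- v[[nm]] / (1 - b2^t)
          w[[nm]] <- w[[nm]] - config$learningRate * mh / (sqrt(vh) + eps)
        }
      }
      testPred <- .forward(w, xTest)$out
      metric <- rSquared(testPred, yTest)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = epochLoss / n,
                                     test_metric = metric))
      if (metric > bestMetric) {
        bestMetric <- metric; best <- w; bestEpoch <- epoch
      }
    }
    new("ScoringNetwork", inputBits = spec$inputBits, hidden = spec$hidden,
        dropout = spec$dropout, weights = best, bestEpoch = bestEpoch,
        history = hist)
  })
}

#' Predict affinities
#'
#' Deterministic forward pass (dropout inactive) of a trained
#' [ScoringNetwork-class].
#'
#' @param model a [ScoringNetwork-class].
#' @param x numeric matrix (rows = samples) or a single fingerprint vector.
#' @return numeric vector of predicted pChEMBL values.
#' @export
predictAffinity <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model@inputBits)
    .stopf("feature width %d does not match model inputBits %d",
           ncol(x), model@inputBits)
  .forward(model@weights, x)$out
}

#' Serialise / restore a scoring network
#'
#' Plain-text archive: a versioned header with the architecture, then flat
#' weight arrays, then the training history as CSV.
#'
#' @param model a [ScoringNetwork-class].
#' @param path file path.
#' @return `writeScoringNetwork`: invisibly, `path`;
#'   `readScoringNetwork`: the restored [ScoringNetwork-class].
#' @export
writeScoringNetwork <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("kindock-scoring-network v1",
               paste(model@inputBits, model@hidden[1], model@hidden[2],
                     model@dropout, model@bestEpoch)), con)
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3"))
    writeLines(paste(format(as.numeric(model@weights[[nm]]), digits = 17),
                     collapse = " "), con)
  writeLines("history", con)
  utils::write.csv(model@history, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScoringNetwork
#' @export
readScoringNetwork <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "kindock-scoring-network v1")
    stop("not a kindock scoring-network archive")
  hdr <- as.numeric(strsplit(lines[2], " ")[[1]])
  dims <- c(hdr[1], hdr[2], hdr[3], 1)
  w <- list()
  for (l in 1:3) {
    w[[paste0("W", l)]] <- matrix(as.numeric(strsplit(trimws(lines[1 + 2 * l]), " +")[[1]]),
                                  nrow = dims[l])
    w[[paste0("b", l)]] <- as.numeric(strsplit(trimws(lines[2 + 2 * l]), " +")[[1]])
  }
  histStart <- which(lines == "history") + 1L
  hist <- utils::read.csv(textConnection(lines[histStart:length(lines)]))
  new("ScoringNetwork", inputBits = as.integer(hdr[1]),
      hidden = as.integer(hdr[2:3]), dropout = hdr[4], weights = w,
      bestEpoch = as.integer(hdr[5]), history = hist)
}
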