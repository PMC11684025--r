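# Docking engine contract and the bundled deterministic mock engine.
#
# The mock engine stands in for external docking programs in tests and toy
# pipelines. It fabricates a rigid 3D conformer directly from the molecular
# graph (spectral layout of the graph Laplacian scaled to bond-length
# scale, plus a seeded jitter to break symmetry) and places seeded
# random rigid copies inside the docking box. Unlike toolkit conformer
# generators, this construction is exactly reproducible, which the
# end-to-end determinism guarantees of the pipeline rely on.

#' The bundled mock docking engine
#'
#' @return a [MockEngine-class] implementing [dockIsomer()].
#' @export
mockEngine <- function() new("MockEngine", name = "mock", needsBox = TRUE)

#' Adapter for an external docking program
#'
#' Wraps a user-installed docking executable behind the engine contract. The
#' adapter function receives `(isomer, structure, box, nPoses, seed)` and
#' must return a list of [LigandPose-class] (typically by writing input
#' files, shelling out to `command`, and reading the poses back with
#' [readPoseMol()]). A missing executable fails with a clear
#' "engine unavailable" error — it never degrades to the mock engine
#' silently.
#'
#' @param name engine label stored with every pose (e.g. "vina-like").
#' @param command executable looked up on `PATH`.
#' @param adapter function implementing the actual call.
#' @param needsBox whether the engine requires a docking box.
#' @return an [ExternalEngine-class].
#' @export
externalEngine <- function(name, command, adapter, needsBox = TRUE) {
  stopifnot(is.function(adapter))
  new("ExternalEngine", name = name, needsBox = needsBox, command = command,
      adapter = adapter)
}

#' @describeIn DockingEngine adapter for an external docking executable
#'   (see [externalEngine()]).
#' @export
setClass("ExternalEngine", contains = "DockingEngine",
         representation(command = "character", adapter = "function"))

#' @rdname externalEngine
#' @inheritParams dockIsomer
#' @export
setMethod("dockIsomer", "ExternalEngine",
          function(engine, isomer, structure, box = NULL, nPoses = 5L, seed = 1L) {
  if (!nzchar(Sys.which(engine@command)))
    .stopf("engine '%s' unavailable: executable '%s' not found on PATH",
           engine@name, engine@command)
  if (engine@needsBox && is.null(box))
    .stopf("engine '%s' requires a docking box", engine@name)
  engine@adapter(isomer = isomer, structure = structure, box = box,
                 nPoses = nPoses, seed = seed)
})

# deterministic rigid conformer from the graph topology
.spectralConformer <- function(graph, seed = 1L) {
  n <- nrow(graph@atoms)
  if (n == 1L) return(matrix(0, 1, 3))
  b <- graph@bonds
  A <- matrix(0, n, n)
  if (nrow(b)) { A[cbind(b$i, b$j)] <- 1; A[cbind(b$j, b$i)] <- 1 }
  L <- diag(rowSums(A)) - A
  ev <- eigen(L, symmetric = TRUE)
  # smallest non-trivial eigenvectors give a low-distortion layout
  idx <- order(ev$values)[2:min(4L, n)]
  X <- matrix(0, n, 3)
  X[, seq_along(idx)] <- ev$vectors[, idx, drop = FALSE]
  # fix eigenvector sign for platform-independence
  for (k in seq_along(idx)) {
    col <- X[, k]
    nz <- which(abs(col) > 1e-12)
    if (length(nz) && col[nz[1]] < 0) X[, k] <- -col
  }
  X <- X + .withSeed(seed, matrix(stats::runif(n * 3, -0.05, 0.05), n, 3))
  # scale so the mean bonded distance is a typical bond length
  if (nrow(b)) {
    d <- sqrt(rowSums((X[b$i, , drop = FALSE] - X[b$j, , drop = FALSE])^2))
    md <- mean(d)
    if (md > 1e-9) X <- X * (1.5 / md)
  }
  sweep(X, 2, colMeans(X))
}

# seeded uniform random rotation matrix
.randomRotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    nq <- sqrt(sum(q^2))
    if (nq > 1e-12) { q <- q / nq; break }
  }
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Mock docking of one isomer
#'
#' Generates `nPoses` rigid copies of the fabricated conformer at seeded
#' random orientations and positions inside the box (pose centroids always
#' inside), with a seeded strictly decreasing engine score by rank. Fully
#' deterministic given `seed`.
#'
#' @inheritParams dockIsomer
#' @export
setMethod("dockIsomer", "MockEngine",
          function(engine, isomer, structure, box = NULL, nPoses = 5L, seed = 1L) {
  if (is.null(box)) stop("the mock engine requires a docking box")
  if (nPoses < 0L) stop("nPoses must be >= 0")
  if (nPoses == 0L) return(list())
  graph <- if (is(isomer, "MolGraph")) isomer else molGraphFromSmiles(isomer)
  conf <- .spectralConformer(graph, seed = seed)
  ligRadius <- max(sqrt(rowSums(conf^2)))
  margin <- box@extents / 2 - ligRadius
  if (any(margin < 0))
    .stopf("docking box (extents %.1f x %.1f x %.1f A) smaller than ligand extent %.1f A",
           box@extents[1], box@extents[2], box@extents[3], ligRadius)
  isoId <- if (is.character(isomer)) isomer else "graph-isomer"
  .withSeed(seed, {
    scores <- -sort(stats::runif(nPoses, 5, 12), decreasing = TRUE)
    poses <- vector("list", nPoses)
    for (k in seq_len(nPoses)) {
      Rm <- .randomRotation()
      center <- box@center + stats::runif(3, -1, 1) * margin
      X <- sweep(conf %*% t(Rm), 2, center, "+")
      poses[[k]] <- new("LigandPose",
                        poseId = sprintf("%s|%s|mock|%d", isoId,
                                         structure@structureId, k),
                        isomerId = isoId,
                        structureId = structure@structureId,
                        engine = engine@name, rank = k,
                        engineScore = scores[k], clashScore = NA_real_,
                        graph = graph, coords = X)
    }
    poses
  })
})
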