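# Symmetry-aware ligand RMSD.

.poseIgraph <- function(pose) {
  g <- pose@graph
  ig <- igraph::graph_from_edgelist(cbind(g@bonds$i, g@bonds$j), directed = FALSE)
  n <- nrow(g@atoms)
  if (igraph::vcount(ig) < n) ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
  ig
}

# integer vertex colors from element + charge
.atomColors <- function(a, levels) {
  match(paste(a$element, a$charge), levels)
}

#' Symmetry-corrected ligand RMSD
#'
#' Root-mean-square deviation between two poses of the same molecule,
#' minimised over the automorphisms of the molecular graph (VF2, atoms
#' coloured by element and charge) so that topologically equivalent atoms
#' -- e.g. the two ortho carbons of a para-substituted ring -- are matched
#' optimally. No re-superposition is performed: docking benchmarks compare
#' poses in the fixed receptor frame.
#'
#' @param poseA,poseB [LigandPose-class] objects with identical molecular
#'   graphs (up to automorphism).
#' @return RMSD in Angstrom.
#' @export
ligandRmsd <- function(poseA, poseB) {
  gA <- poseA@graph; gB <- poseB@graph
  if (nrow(gA@atoms) != nrow(gB@atoms) || nrow(gA@bonds) != nrow(gB@bonds))
    stop("molecular graphs differ: atom/bond counts do not match")
  levels <- unique(c(paste(gA@atoms$element, gA@atoms$charge),
                     paste(gB@atoms$element, gB@atoms$charge)))
  igA <- .poseIgraph(poseA); igB <- .poseIgraph(poseB)
  maps <- igraph::graph.get.isomorphisms.vf2(
    igA, igB,
    vertex.color1 = .atomColors(gA@atoms, levels),
    vertex.color2 = .atomColors(gB@atoms, levels))
  if (!length(maps)) stop("molecular graphs differ: no isomorphism found")
  A <- poseCoords(poseA); B <- poseCoords(poseB)
  best <- Inf
  for (m in maps) {
    perm <- as.integer(m)
    v <- sqrt(mean(rowSums((A - B[perm, , drop = FALSE])^2)))
    if (v < best) best <- v
  }
  best
}
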