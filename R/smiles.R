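# SMILES handling. Parsing, kekulization and canonicalisation are delegated
# to OpenBabel (ChemmineR/ChemmineOB); the token scanner below exists only to
# recover per-atom annotations that the kekulized SDF route loses (aromatic
# flags, bracket H counts, charges, stereo marks) and to locate atom tokens
# for stereoisomer enumeration. Atom order is identical between a SMILES
# string and the SDF OpenBabel builds from it; this is asserted at run time.

.ELEMENTS2 <- c("Cl", "Br", "Si", "Se", "As", "Li", "Na", "Mg", "Ca", "Fe", "Zn")
.ORGANIC1 <- c("B", "C", "N", "O", "P", "S", "F", "I")
.AROMATIC_TOK <- c("b", "c", "n", "o", "p", "s")

.DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                      F = 1, Cl = 1, Br = 1, I = 1)

#' Canonical SMILES
#'
#' Canonicalise a SMILES string with OpenBabel, preserving stereochemistry.
#' Non-stereogenic stereo marks are dropped by the canonicaliser, which
#' [enumerateIsomers()] exploits for deduplication.
#'
#' @param smiles a single SMILES string.
#' @return canonical (isomeric) SMILES.
#' @export
canonicalSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) "")
  out <- sub("[ \t\r\n]+$", "", out)
  out <- sub("[\t ].*$", "", out)  # strip any title field
  if (!nzchar(out)) .stopf("SMILES cannot be parsed: '%s'", smiles)
  out
}

# Scan a SMILES string into tokens. Returns a data.frame with one row per
# token: type ("atom", "bond", "open", "close", "ring"), start/end character
# positions, and for atom tokens the element, aromatic flag, charge,
# bracket H count (NA outside brackets) and stereo mark ("", "@", "@@").
.smilesTokens <- function(s) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  rows <- list()
  i <- 1L
  push <- function(type, start, end, element = NA, aromatic = NA, charge = NA,
                   hcount = NA, stereo = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, start = start, end = end, element = element,
      aromatic = aromatic, charge = charge, hcount = hcount,
      stereo = stereo, stringsAsFactors = FALSE)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) .stopf("unclosed bracket atom in SMILES at position %d", i)
      body <- substr(s, i + 1L, j - 1L)
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H[0-9]*)?([+-][0-9]*|[+]+|[-]+)?$", body))[[1]]
      if (length(m) == 0L) .stopf("cannot scan bracket atom '[%s]'", body)
      elem <- m[3]
      arom <- elem == tolower(elem)
      if (arom) elem <- paste0(toupper(substr(elem, 1, 1)), substr(elem, 2, nchar(elem)))
      hc <- if (is.na(m[5]) || m[5] == "") 0L
            else if (m[5] == "H") 1L else as.integer(substr(m[5], 2, nchar(m[5])))
      chg <- 0L
      if (!is.na(m[6]) && nzchar(m[6])) {
        cm <- m[6]
        if (grepl("^[+-][0-9]+$", cm)) chg <- as.integer(cm)
        else chg <- (nchar(cm)) * ifelse(substr(cm, 1, 1) == "+", 1L, -1L)
      }
      push("atom", i, j, elem, arom, chg, hc, m[4])
      i <- j + 1L
    } else if (i < n && substr(s, i, i + 1L) %in% .ELEMENTS2) {
      push("atom", i, i + 1L, substr(s, i, i + 1L), FALSE, 0L)
      i <- i + 2L
    } else if (ch %in% .ORGANIC1) {
      push("atom", i, i, ch, FALSE, 0L)
      i <- i + 1L
    } else if (ch %in% .AROMATIC_TOK) {
      push("atom", i, i, toupper(ch), TRUE, 0L)
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\", "~")) {
      push("bond", i, i)
      i <- i + 1L
    } else if (ch == "(") { push("open", i, i); i <- i + 1L
    } else if (ch == ")") { push("close", i, i); i <- i + 1L
    } else if (ch == "%") {
      push("ring", i, i + 2L); i <- i + 3L
    } else if (grepl("[0-9]", ch)) {
      push("ring", i, i); i <- i + 1L
    } else if (ch == ".") { push("open", i, i); i <- i + 1L  # fragment separator
    } else .stopf("unexpected character '%s' in SMILES at position %d", ch, i)
  }
  do.call(rbind, rows)
}

# Implicit hydrogen count from kekulized bond orders and standard valences.
.implicitH <- function(element, charge, bondOrderSum) {
  v <- .DEFAULT_VALENCE[element]
  if (is.na(v)) return(0L)
  v <- v + charge  # N+ -> 4, O- -> 1; adequate for the organic subset handled
  max(0L, as.integer(v - bondOrderSum))
}

#' Build a molecular graph from SMILES
#'
#' Canonicalises the SMILES, builds the kekulized connection table with
#' OpenBabel, and annotates atoms with aromaticity, formal charge and
#' attached-hydrogen counts recovered from the canonical string (bracket H
#' counts where explicit, standard-valence arithmetic otherwise).
#'
#' @param smiles a single SMILES string.
#' @return a [MolGraph-class] whose atom order matches the canonical SMILES.
#' @export
molGraphFromSmiles <- function(smiles) {
  can <- canonicalSmiles(smiles)
  tok0 <- .smilesTokens(can)
  atok0 <- tok0[tok0$type == "atom", , drop = FALSE]
  if (nrow(atok0) == 1L) {
    # single-atom molecule: the SDF route cannot represent a bondless block
    nH <- if (!is.na(atok0$hcount[1])) as.integer(atok0$hcount[1])
          else .implicitH(atok0$element[1], atok0$charge[1], 0)
    g <- new("MolGraph",
             atoms = data.frame(element = atok0$element[1],
                                charge = as.integer(atok0$charge[1]),
                                aromatic = as.logical(atok0$aromatic[1]),
                                nH = nH, stringsAsFactors = FALSE),
             bonds = data.frame(i = integer(), j = integer(), order = integer()))
    attr(g, "smiles") <- can
    return(g)
  }
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(can)),
                  error = function(e) .stopf("SMILES cannot be parsed: '%s'", smiles))
  sdfObj <- sdf[[1]]
  ab <- ChemmineR::atomblock(sdfObj)
  bb <- ChemmineR::bondblock(sdfObj)
  elements <- sub("_.*$", "", rownames(ab))
  tok <- .smilesTokens(can)
  atok <- tok[tok$type == "atom", , drop = FALSE]
  if (nrow(atok) != length(elements) || !all(atok$element == elements))
    .stopf("internal atom-order mismatch between SMILES and SDF for '%s'", can)
  bondsDf <- if (is.null(nrow(bb)) || nrow(bb) == 0L)
    data.frame(i = integer(), j = integer(), order = integer())
  else data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                  order = as.integer(bb[, 3]))
  ordSum <- numeric(length(elements))
  if (nrow(bondsDf)) for (k in seq_len(nrow(bondsDf))) {
    ordSum[bondsDf$i[k]] <- ordSum[bondsDf$i[k]] + bondsDf$order[k]
    ordSum[bondsDf$j[k]] <- ordSum[bondsDf$j[k]] + bondsDf$order[k]
  }
  nH <- integer(length(elements))
  for (a in seq_along(elements)) {
    nH[a] <- if (!is.na(atok$hcount[a])) as.integer(atok$hcount[a])
             else .implicitH(elements[a], atok$charge[a], ordSum[a])
  }
  g <- new("MolGraph",
           atoms = data.frame(element = elements,
                              charge = as.integer(atok$charge),
                              aromatic = as.logical(atok$aromatic),
                              nH = nH, stringsAsFactors = FALSE),
           bonds = bondsDf)
  attr(g, "smiles") <- can
  g
}

#' Heavy-atom degree
#'
#' @param graph a [MolGraph-class].
#' @return integer vector, one entry per atom.
#' @export
heavyDegree <- function(graph) {
  d <- integer(nrow(graph@atoms))
  b <- graph@bonds
  if (nrow(b)) {
    t1 <- table(factor(b$i, levels = seq_along(d)))
    t2 <- table(factor(b$j, levels = seq_along(d)))
    d <- as.integer(t1 + t2)
  }
  d
}

#' Ring membership
#'
#' Flags atoms that lie on any cycle, via the biconnected components of the
#' molecular graph.
#'
#' @param graph a [MolGraph-class].
#' @return logical vector, one entry per atom.
#' @export
ringMembership <- function(graph) {
  n <- nrow(graph@atoms)
  out <- logical(n)
  b <- graph@bonds
  if (!nrow(b)) return(out)
  ig <- igraph::graph_from_edgelist(cbind(b$i, b$j), directed = FALSE)
  if (igraph::vcount(ig) < n) ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
  bc <- igraph::biconnected_components(ig)
  for (comp in bc$components) {
    idx <- as.integer(comp)
    # a biconnected block with >= 3 vertices contains a cycle
    if (length(idx) >= 3L) out[idx] <- TRUE
  }
  out
}

#' Embed a molecule in 3D
#'
#' Delegates to OpenBabel's standard 3D builder (`gen3d`). Note the builder's
#' conformer search is stochastic: repeated calls can return different
#' conformers. Reproducible pipelines should embed once and persist the
#' result (the pose database does this), or use engines that fabricate their
#' own conformers (the mock engine).
#'
#' @param smiles isomeric SMILES.
#' @return character scalar, an MDL MOL block with 3D coordinates.
#' @export
embedMolecule <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "SDF", smiles, options = data.frame(names = "gen3d", args = ""))),
    error = function(e) "")
  if (!nzchar(out)) .stopf("3D embedding failed for '%s'", smiles)
  sub("\\$\\$\\$\\$[[:space:]]*$", "", out)
}
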