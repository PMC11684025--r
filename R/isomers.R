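# Stereoisomer enumeration.
#
# No installed toolkit interface exposes stereoisomer enumeration, so it is
# done by token surgery on the canonical SMILES: every unassigned candidate
# tetrahedral centre gets both @/@@ marks and every unassigned acyclic C=C
# both cis/trans marker patterns; each assignment is re-canonicalised with
# OpenBabel, which drops marks on non-stereogenic atoms, so false candidates
# collapse during deduplication and only genuine stereoisomers survive.

# Walk the token stream and record the implicitly written chain bonds:
# (u, v) atom ordinals, the insertion position just before v's token, and
# any bond symbol character directly preceding v.
.chainBonds <- function(tok) {
  res <- list()
  stack <- integer()
  prev <- NA_integer_
  atomOrd <- 0L
  lastBondChar <- ""
  lastBondPos <- NA_integer_
  for (k in seq_len(nrow(tok))) {
    t <- tok[k, ]
    if (t$type == "atom") {
      atomOrd <- atomOrd + 1L
      if (!is.na(prev)) {
        res[[length(res) + 1L]] <- data.frame(
          u = prev, v = atomOrd,
          insertPos = if (is.na(lastBondPos)) t$start else lastBondPos,
          bondChar = lastBondChar, stringsAsFactors = FALSE)
      }
      prev <- atomOrd
      lastBondChar <- ""; lastBondPos <- NA_integer_
    } else if (t$type == "bond") {
      lastBondChar <- substr(attr(tok, "smiles"), t$start, t$end)
      lastBondPos <- t$start
    } else if (t$type == "open") {
      stack <- c(stack, prev)
      if (substr(attr(tok, "smiles"), t$start, t$end) == ".") prev <- NA_integer_
    } else if (t$type == "close") {
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    }
    # ring tokens: closure bonds carry no usable insertion anchor; skipped
  }
  if (length(res)) do.call(rbind, res)
  else data.frame(u = integer(), v = integer(), insertPos = integer(),
                  bondChar = character())
}

# Rebuild a bracket atom token with a stereo mark from token annotations.
.stereoToken <- function(element, aromatic, charge, nH, mark) {
  el <- if (aromatic) tolower(element) else element
  hpart <- if (nH >= 2L) paste0("H", nH) else if (nH == 1L) "H" else ""
  cpart <- if (charge > 0L) paste0("+", if (charge > 1L) charge else "")
           else if (charge < 0L) paste0("-", if (charge < -1L) -charge else "")
           else ""
  paste0("[", el, mark, hpart, cpart, "]")
}

#' Enumerate stereoisomers of a compound
#'
#' Enumerates all combinations of the unassigned tetrahedral centres and
#' unassigned acyclic double-bond geometries of a molecule, preserving any
#' stereochemistry already specified. The result is deduplicated by
#' canonical isomeric SMILES and capped.
#'
#' @param smiles input SMILES.
#' @param maxIsomers cap on the number of returned isomers (default 32);
#'   a warning is emitted when enumeration is truncated.
#' @return character vector of canonical isomeric SMILES (at least 1).
#' @examples
#' enumerateIsomers("CC(F)Cl")   # one unassigned centre -> 2 enantiomers
#' enumerateIsomers("C/C=C/C")   # geometry fixed        -> 1
#' @export
enumerateIsomers <- function(smiles, maxIsomers = 32L) {
  can <- canonicalSmiles(smiles)
  g <- molGraphFromSmiles(can)
  tok <- .smilesTokens(can)
  attr(tok, "smiles") <- can
  atok <- tok[tok$type == "atom", , drop = FALSE]
  deg <- heavyDegree(g)
  ring <- ringMembership(g)
  chain <- .chainBonds(tok)

  # candidate tetrahedral centres: sp3 carbon, no mark yet, 4 substituents
  tetra <- which(g@atoms$element == "C" & !g@atoms$aromatic & atok$stereo == "" &
                 ((deg == 3L & g@atoms$nH == 1L) | (deg == 4L & g@atoms$nH == 0L)))
  # drop carbons involved in any multiple bond
  if (length(tetra) && nrow(g@bonds)) {
    multi <- unique(c(g@bonds$i[g@bonds$order > 1L], g@bonds$j[g@bonds$order > 1L]))
    tetra <- setdiff(tetra, multi)
  }

  # candidate stereogenic double bonds: acyclic C=C with single-bond anchors
  # writable in the token stream and no directional mark already present
  dbonds <- list()
  if (nrow(g@bonds)) {
    bkey <- function(u, v) paste(pmin(u, v), pmax(u, v))
    orderOf <- structure(g@bonds$order, names = bkey(g@bonds$i, g@bonds$j))
    for (k in which(g@bonds$order == 2L)) {
      a <- g@bonds$i[k]; b <- g@bonds$j[k]
      if (ring[a] || ring[b]) next
      if (g@atoms$element[a] != "C" || g@atoms$element[b] != "C") next
      if (g@atoms$aromatic[a] || g@atoms$aromatic[b]) next
      if (g@atoms$nH[a] >= 2L || g@atoms$nH[b] >= 2L) next  # terminal =CH2: no geometry
      anchorFor <- function(atom, other) {
        cand <- chain[(chain$u == atom | chain$v == atom) &
                      !(chain$u %in% c(atom, other) & chain$v %in% c(atom, other)), ,
                      drop = FALSE]
        if (!nrow(cand)) return(NULL)
        cand$ord <- orderOf[bkey(cand$u, cand$v)]
        cand <- cand[!is.na(cand$ord) & cand$ord == 1L, , drop = FALSE]
        if (!nrow(cand)) return(NULL)
        cand[1L, ]
      }
      aa <- anchorFor(a, b); ab <- anchorFor(b, a)
      if (is.null(aa) || is.null(ab)) next
      inc <- chain[(chain$u %in% c(a, b) | chain$v %in% c(a, b)), , drop = FALSE]
      if (any(inc$bondChar %in% c("/", "\\"))) next  # geometry already assigned
      dbonds[[length(dbonds) + 1L]] <- list(posA = aa$insertPos, posB = ab$insertPos)
    }
  }

  nSites <- length(tetra) + length(dbonds)
  if (nSites == 0L) return(can)

  maxSites <- max(0L, floor(log2(max(1, maxIsomers))))
  truncated <- FALSE
  if (nSites > maxSites) {
    truncated <- TRUE
    keepT <- head(tetra, maxSites)
    keepD <- head(dbonds, max(0L, maxSites - length(keepT)))
    tetra <- keepT; dbonds <- keepD
    nSites <- length(tetra) + length(dbonds)
  }

  combos <- expand.grid(rep(list(c(FALSE, TRUE)), nSites))
  out <- character(0)
  for (r in seq_len(nrow(combos))) {
    flags <- as.logical(combos[r, ])
    edits <- list()  # (start, end, text); end < start means pure insertion
    for (s in seq_along(tetra)) {
      a <- tetra[s]
      mark <- if (flags[s]) "@@" else "@"
      edits[[length(edits) + 1L]] <- list(
        start = atok$start[a], end = atok$end[a],
        text = .stereoToken(g@atoms$element[a], g@atoms$aromatic[a],
                            g@atoms$charge[a], g@atoms$nH[a], mark))
    }
    for (s in seq_along(dbonds)) {
      f <- flags[length(tetra) + s]
      db <- dbonds[[s]]
      edits[[length(edits) + 1L]] <- list(start = db$posA, end = db$posA - 1L, text = "/")
      edits[[length(edits) + 1L]] <- list(start = db$posB, end = db$posB - 1L,
                                          text = if (f) "\\" else "/")
    }
    ord <- order(vapply(edits, `[[`, numeric(1), "start"), decreasing = TRUE)
    s2 <- can
    for (e in edits[ord]) {
      s2 <- paste0(substr(s2, 1L, e$start - 1L), e$text,
                   substr(s2, e$end + 1L, nchar(s2)))
    }
    cs <- tryCatch(canonicalSmiles(s2), error = function(e) NA_character_)
    if (!is.na(cs)) out <- c(out, cs)
  }
  out <- sort(unique(out))
  if (!length(out)) out <- can
  if (length(out) > maxIsomers) {
    out <- out[seq_len(maxIsomers)]
    truncated <- TRUE
  }
  if (truncated)
    warning(sprintf("isomer enumeration for '%s' truncated at %d", can, maxIsomers))
  out
}
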