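# Structure and pose I/O: PDB via bio3d, MDL MOL/SDF via ChemmineR,
# zlib compression for database storage.

#' Read a protein structure from PDB text
#'
#' Parses PDB text (or a file path) with bio3d and returns the protein
#' atoms. By default only `ATOM` records are used; `includeHet = TRUE` also
#' keeps `HETATM` records.
#'
#' @param text PDB file content as a single string or character vector of
#'   lines; alternatively a path to a PDB file via `file`.
#' @param file optional path (mutually exclusive with `text`).
#' @param structureId identifier stored in the returned object.
#' @param includeHet keep HETATM records too?
#' @return a [ProteinStructure-class].
#' @export
readProteinPdb <- function(text = NULL, file = NULL, structureId = "protein",
                           includeHet = FALSE) {
  if (is.null(text) == is.null(file)) stop("supply exactly one of 'text' or 'file'")
  if (!is.null(text)) {
    lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  } else lines <- readLines(file)
  # pre-validate coordinate records so malformed input fails with a line number
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (k in which(rec)) {
    ln <- lines[k]
    if (nchar(ln) < 54)
      .stopf("malformed PDB coordinate record at line %d (too short)", k)
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      .stopf("malformed PDB coordinate record at line %d (bad coordinates)", k)
  }
  if (!any(rec)) .stopf("no coordinate records found in PDB input")
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE)
  at <- pdb$atom
  if (!includeHet) at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) .stopf("no protein ATOM records in PDB input")
  elem <- at$elesy
  miss <- is.na(elem) | !nzchar(trimws(elem))
  if (any(miss)) elem[miss] <- substr(trimws(at$elety[miss]), 1, 1)
  new("ProteinStructure", structureId = structureId,
      atoms = data.frame(element = trimws(elem), x = at$x, y = at$y, z = at$z,
                         resno = at$resno, resname = trimws(at$resid),
                         stringsAsFactors = FALSE))
}

# counts-line sanity check giving a line-numbered error before delegating
.checkMolCounts <- function(lines) {
  if (length(lines) < 4L) .stopf("malformed MOL block: fewer than 4 lines")
  cl <- lines[4]
  na <- suppressWarnings(as.integer(substr(cl, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(cl, 4, 6)))
  if (is.na(na) || is.na(nb))
    .stopf("malformed MOL counts line at line 4: '%s'", cl)
  if (length(lines) < 4L + na + nb)
    .stopf("malformed MOL block: %d atoms + %d bonds declared but only %d lines",
           na, nb, length(lines))
  for (k in seq_len(na)) {
    ln <- lines[4L + k]
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 1, 10), substr(ln, 11, 20),
                                         substr(ln, 21, 30))))
    if (anyNA(xyz)) .stopf("malformed MOL atom record at line %d", 4L + k)
  }
  c(na, nb)
}

#' Read a ligand pose from MOL/SDF text
#'
#' Parses a single MDL MOL V2000 block (ChemmineR) into a
#' [LigandPose-class]. Pose metadata absent from the file is filled with
#' the supplied identifiers.
#'
#' @param text MOL block as one string or character vector of lines.
#' @param poseId,isomerId,structureId,engine identifiers for the pose.
#' @param rank engine rank; `engineScore` engine-native score.
#' @param engineScore engine-native score.
#' @return a [LigandPose-class].
#' @export
readPoseMol <- function(text, poseId = "pose", isomerId = "isomer",
                        structureId = "structure", engine = "unknown",
                        rank = 1L, engineScore = NA_real_) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  counts <- .checkMolCounts(lines)
  if (counts[2] == 0L) {
    # bond-less blocks (single atoms, fragments) read directly: the SDF
    # toolkit cannot index a molecule without a bond block
    na <- counts[1]
    al <- lines[4L + seq_len(na)]
    X <- cbind(as.numeric(substr(al, 1, 10)), as.numeric(substr(al, 11, 20)),
               as.numeric(substr(al, 21, 30)))
    elements <- trimws(substr(al, 31, 34))
    g <- new("MolGraph",
             atoms = data.frame(element = elements, charge = 0L,
                                aromatic = FALSE, nH = 0L,
                                stringsAsFactors = FALSE),
             bonds = data.frame(i = integer(), j = integer(), order = integer()))
    return(new("LigandPose", poseId = poseId, isomerId = isomerId,
               structureId = structureId, engine = engine,
               rank = as.integer(rank), engineScore = engineScore,
               clashScore = NA_real_, graph = g, coords = X))
  }
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  body <- lines
  if (!any(grepl("^\\$\\$\\$\\$", body))) body <- c(body, "$$$$")
  writeLines(body, tf)
  sset <- ChemmineR::read.SDFset(tf)
  sdf <- sset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  bondsDf <- if (is.null(nrow(bb)) || nrow(bb) == 0L)
    data.frame(i = integer(), j = integer(), order = integer())
  else data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                  order = as.integer(bb[, 3]))
  g <- new("MolGraph",
           atoms = data.frame(element = elements,
                              charge = rep(0L, length(elements)),
                              aromatic = rep(FALSE, length(elements)),
                              nH = rep(0L, length(elements)),
                              stringsAsFactors = FALSE),
           bonds = bondsDf)
  new("LigandPose", poseId = poseId, isomerId = isomerId,
      structureId = structureId, engine = engine, rank = as.integer(rank),
      engineScore = engineScore, clashScore = NA_real_, graph = g,
      coords = unname(as.matrix(ab[, 1:3, drop = FALSE])))
}

#' Write a ligand pose as MOL text
#'
#' Serialises a [LigandPose-class] to an MDL MOL V2000 block (4-decimal
#' coordinates). `readPoseMol(writePoseMol(p))` preserves elements,
#' coordinates (to format precision) and bonds.
#'
#' @param pose a [LigandPose-class].
#' @return character scalar, the MOL block.
#' @export
writePoseMol <- function(pose) {
  a <- atoms(pose); b <- bonds(pose); X <- poseCoords(pose)
  header <- c(pose@poseId, "  kindock", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b))
  atomLines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       X[, 1], X[, 2], X[, 3], a$element)
  bondLines <- if (nrow(b)) sprintf("%3d%3d%3d  0  0  0  0", b$i, b$j, b$order)
               else character(0)
  paste(c(header, counts, atomLines, bondLines, "M  END", ""), collapse = "\n")
}

#' Write a protein structure as PDB text
#'
#' Serialises a [ProteinStructure-class] to standard `ATOM` records
#' (element symbols right-justified in columns 77-78), readable by
#' [readProteinPdb()].
#'
#' @param protein a [ProteinStructure-class].
#' @return character scalar of PDB text.
#' @export
writeProteinPdb <- function(protein) {
  a <- atoms(protein)
  name <- substr(paste0(a$element, seq_len(nrow(a))), 1, 4)
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(a)), name, a$resname, a$resno, a$x, a$y, a$z, a$element)
  paste(c(lines, "END", ""), collapse = "\n")
}

#' Compress / decompress a MOL block for database storage
#'
#' zlib compression of pose text, as stored in the `poses` table.
#'
#' @param text MOL block text.
#' @return `compressMolblock`: raw vector; `decompressMolblock`: the text.
#' @export
compressMolblock <- function(text) {
  memCompress(charToRaw(text), type = "gzip")
}

#' @rdname compressMolblock
#' @param blob raw vector produced by [compressMolblock()].
#' @export
decompressMolblock <- function(blob) {
  rawToChar(memDecompress(blob, type = "gzip"))
}
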