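# SQLite pose database: six relational tables with enforced foreign keys,
# pose mol-blocks stored zlib-compressed.

.DB_SCHEMA <- c(
  proteins = "CREATE TABLE proteins (
      accession TEXT PRIMARY KEY,
      gene TEXT,
      kinase_group TEXT)",
  structures = "CREATE TABLE structures (
      structure_id TEXT PRIMARY KEY,
      accession TEXT NOT NULL REFERENCES proteins(accession),
      pdb_code TEXT,
      resolution REAL,
      quality_score REAL,
      missing_residues INTEGER,
      dfg_state TEXT,
      ac_helix_state TEXT,
      pdb_text TEXT)",
  compounds = "CREATE TABLE compounds (
      compound_id TEXT PRIMARY KEY,
      smiles TEXT NOT NULL,
      mw REAL, hbd INTEGER, hba INTEGER, rotb INTEGER)",
  isomers = "CREATE TABLE isomers (
      isomer_id TEXT PRIMARY KEY,
      compound_id TEXT NOT NULL REFERENCES compounds(compound_id),
      isomeric_smiles TEXT NOT NULL)",
  activities = "CREATE TABLE activities (
      activity_id TEXT PRIMARY KEY,
      compound_id TEXT NOT NULL REFERENCES compounds(compound_id),
      accession TEXT NOT NULL REFERENCES proteins(accession),
      pchembl REAL,
      activity_type TEXT)",
  poses = "CREATE TABLE poses (
      pose_id TEXT PRIMARY KEY,
      isomer_id TEXT NOT NULL REFERENCES isomers(isomer_id),
      structure_id TEXT NOT NULL REFERENCES structures(structure_id),
      engine TEXT NOT NULL,
      rank INTEGER NOT NULL,
      engine_score REAL,
      clash_score REAL,
      molblock_z BLOB,
      molblock_n INTEGER,
      UNIQUE (isomer_id, structure_id, engine, rank))")

#' Initialise (or open) a pose database
#'
#' Creates the six-table schema (proteins, structures, compounds, isomers,
#' activities, poses) in an SQLite file with foreign-key enforcement on; an
#' existing kindock database is opened as is.
#'
#' @param path database file path (":memory:" for transient use).
#' @return a [PoseDB-class] handle.
#' @export
dbInit <- function(path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  have <- DBI::dbListTables(con)
  for (t in names(.DB_SCHEMA))
    if (!t %in% have) DBI::dbExecute(con, .DB_SCHEMA[[t]])
  new("PoseDB", con = con, path = path)
}

#' Close a pose database
#'
#' @param db a [PoseDB-class].
#' @export
dbClose <- function(db) {
  if (DBI::dbIsValid(db@con)) DBI::dbDisconnect(db@con)
  invisible(NULL)
}

.dbCheckOpen <- function(db) {
  if (!DBI::dbIsValid(db@con)) stop("pose database connection is closed")
}

#' Store records in a pose database table
#'
#' Appends rows to one of the six tables. Pose rows may carry a `molblock`
#' text column, which is zlib-compressed into `molblock_z` (with the
#' uncompressed size in `molblock_n`) before storage. Foreign-key
#' violations fail with the name of the missing parent.
#'
#' @param db a [PoseDB-class].
#' @param table one of "proteins", "structures", "compounds", "isomers",
#'   "activities", "poses".
#' @param rows data.frame of rows matching the table's columns.
#' @return invisibly, the number of rows written.
#' @export
dbStore <- function(db, table, rows) {
  .dbCheckOpen(db)
  table <- match.arg(table, names(.DB_SCHEMA))
  if (!nrow(rows)) return(invisible(0L))
  if (table == "poses" && "molblock" %in% names(rows)) {
    rows$molblock_z <- I(lapply(rows$molblock, compressMolblock))
    rows$molblock_n <- nchar(rows$molblock, type = "bytes")
    rows$molblock <- NULL
  }
  cols <- DBI::dbListFields(db@con, table)
  rows <- rows[, intersect(cols, names(rows)), drop = FALSE]
  tryCatch(
    DBI::dbAppendTable(db@con, table, rows),
    error = function(e) {
      msg <- conditionMessage(e)
      if (grepl("FOREIGN KEY", msg, ignore.case = TRUE)) {
        parents <- c(structures = "proteins", isomers = "compounds",
                     activities = "compounds/proteins",
                     poses = "isomers/structures")
        .stopf("foreign-key violation inserting into '%s': missing parent row in %s",
               table, parents[[table]])
      }
      stop(e)
    })
  invisible(nrow(rows))
}

#' Load records from a pose database
#'
#' Reads a whole table (or the rows matching a WHERE clause); pose
#' mol-blocks are transparently decompressed back into a `molblock` text
#' column.
#'
#' @param db a [PoseDB-class].
#' @param table table name.
#' @param where optional SQL WHERE clause body (without the keyword).
#' @param params optional parameter list for `?` placeholders in `where`.
#' @return data.frame.
#' @export
dbLoad <- function(db, table, where = NULL, params = NULL) {
  .dbCheckOpen(db)
  table <- match.arg(table, names(.DB_SCHEMA))
  sql <- paste0("SELECT * FROM ", table,
                if (!is.null(where)) paste0(" WHERE ", where) else "")
  out <- DBI::dbGetQuery(db@con, sql, params = params)
  if (table == "poses" && nrow(out) && "molblock_z" %in% names(out)) {
    out$molblock <- vapply(out$molblock_z, function(b)
      if (is.null(b) || !length(b)) NA_character_ else decompressMolblock(b),
      character(1))
  }
  out
}

#' Audit database referential integrity
#'
#' Runs SQLite's foreign-key check plus the pose uniqueness constraint
#' audit over the whole database.
#'
#' @param db a [PoseDB-class].
#' @return list with `ok` (logical), `fk_violations` (data.frame from
#'   `PRAGMA foreign_key_check`) and `duplicate_pose_keys` (count).
#' @export
dbAudit <- function(db) {
  .dbCheckOpen(db)
  fk <- DBI::dbGetQuery(db@con, "PRAGMA foreign_key_check")
  dup <- DBI::dbGetQuery(db@con,
    "SELECT COUNT(*) AS n FROM (
       SELECT isomer_id, structure_id, engine, rank, COUNT(*) AS c
       FROM poses GROUP BY isomer_id, structure_id, engine, rank
       HAVING c > 1)")$n
  list(ok = nrow(fk) == 0L && dup == 0L, fk_violations = fk,
       duplicate_pose_keys = dup)
}

#' Store a curated dataset in the pose database
#'
#' Writes the compounds, activities and structures of a
#' [CuratedDataset-class] into the relational schema (kinases become
#' `proteins` rows keyed by accession).
#'
#' @param db a [PoseDB-class].
#' @param dataset a [CuratedDataset-class].
#' @return invisibly, `db`.
#' @export
dbStoreDataset <- function(db, dataset) {
  st <- structures(dataset)
  prot <- unique(data.frame(accession = st$accession,
                            gene = NA_character_,
                            kinase_group = if ("kinase_group" %in% names(st))
                              st$kinase_group else NA_character_,
                            stringsAsFactors = FALSE))
  have <- dbLoad(db, "proteins")$accession
  dbStore(db, "proteins", prot[!prot$accession %in% have, , drop = FALSE])
  haveS <- dbLoad(db, "structures")$structure_id
  dbStore(db, "structures",
          st[!st$structure_id %in% haveS, , drop = FALSE])
  cp <- compounds(dataset)
  haveC <- dbLoad(db, "compounds")$compound_id
  dbStore(db, "compounds", cp[!cp$compound_id %in% haveC, , drop = FALSE])
  act <- activities(dataset)
  if (nrow(act)) {
    act$activity_id <- paste(act$compound_id, act$accession, sep = "|")
    act$activity_type <- "pchembl_mean"
    haveA <- dbLoad(db, "activities")$activity_id
    dbStore(db, "activities", act[!act$activity_id %in% haveA, , drop = FALSE])
  }
  invisible(db)
}
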