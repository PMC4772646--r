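## The user-facing entity surface: a ChebiEntity constructed from a
## textual identifier, whose getters read through the merged group.
##
## Merged-group semantics: scalar fields come from the PRIMARY record
## of the group (getId/getParentId reflect the requested record
## itself, so callers can detect deprecation); list-valued getters
## return the ordered union over all group members -- primary first,
## then secondaries in ascending id, file order within a member --
## deduplicated keeping the first occurrence.  Absent values are typed
## NA, never empty text.

## Shared per-directory release store, so constructing many entities
## parses each release once.
.releaseStore <- new.env(parent = emptyenv())

#' Load (and memoise) a release directory
#'
#' Parses the flat files under `dir` into a [ChebiRelease-class],
#' caching the result per normalised path so repeated entity
#' construction reuses one shared index.
#'
#' @param dir Release directory containing decompressed flat files.
#' @param reload Force a re-parse even if already cached.
#' @param ... Passed to [parseRelease()].
#' @return A [ChebiRelease-class].
#' @export
loadRelease <- function(dir, reload = FALSE, ...) {
  key <- normalizePath(dir, mustWork = TRUE)
  if (!reload && !is.null(.releaseStore[[key]]))
    return(.releaseStore[[key]])
  idx <- parseRelease(releasePaths(dir), ...)
  .releaseStore[[key]] <- idx
  idx
}

#' Load a release through the cache
#'
#' Ensures the eight in-memory tables are present locally (fetching
#' any that are missing or stale) and parses them.  The structures and
#' references files are only fetched later, on first use by a
#' structure or reference getter.
#'
#' @param config A [cacheConfig()].
#' @param ... Passed to [parseRelease()].
#' @return A [ChebiRelease-class].
#' @export
releaseFromCache <- function(config, ...) {
  resident <- setdiff(chebiFileNames(), c("structures", "reference"))
  paths <- vapply(resident, function(nm)
    ensureFile(nm, config)@localPath, "")
  idx <- parseRelease(paths, ...)
  ## record where streamed files will live once fetched; fetch lazily
  idx@structuresPath <- file.path(config@cacheDir,
                                  .chebiFileName("structures"))
  idx@referencesPath <- file.path(config@cacheDir,
                                  .chebiFileName("reference"))
  attr(idx, "cacheConfig") <- config
  idx
}

#' Construct a chemical-entity handle
#'
#' The primary entry point.  `identifier` may be `"CHEBI:<n>"`
#' (case-insensitive), a bare digit string or a whole number; all forms
#' denote the same entity.  A secondary (merged) identifier resolves
#' transparently to its primary entry.
#'
#' @param identifier Textual or numeric ChEBI identifier.
#' @param release A [ChebiRelease-class], or a release directory path
#'   (parsed once and shared via [loadRelease()]).
#' @return A [ChebiEntity-class].
#' @section Errors: `chebi_malformed_id` for syntactically invalid
#'   input; `chebi_undefined_id` for an id absent from the release.
#' @examples
#' rel <- canonicalMiniRelease()
#' e <- ChebiEntity("CHEBI:3", rel$dir)
#' getName(e)
#' getCharge(e)
#' @export
ChebiEntity <- function(identifier, release) {
  id <- parseChebiId(identifier)
  if (is.character(release))
    release <- loadRelease(release)
  stopifnot(is(release, "ChebiRelease"))
  primary <- resolvePrimary(release, id)
  new("ChebiEntity", requestedId = id, primaryId = primary,
      release = release)
}

## ---- internal helpers ----

.compoundRow <- function(release, id) {
  release@compounds[release@compounds$ID == id, , drop = FALSE]
}

## Rows of `df` for the group members, member order then file order.
.groupRows <- function(df, members, idCol = "COMPOUND_ID") {
  rows <- do.call(rbind, lapply(members, function(m)
    df[df[[idCol]] == m, , drop = FALSE]))
  if (is.null(rows)) rows <- df[0L, , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

.members <- function(e) groupMembers(e@release, e@primaryId)

## First chemical-data value of a given type over the group, in member
## order (primary first, then ascending id).
.chemValue <- function(e, type) {
  rows <- .groupRows(e@release@chemicalData, .members(e))
  rows <- rows[rows$TYPE == type, , drop = FALSE]
  if (!nrow(rows)) return(NULL)
  rows[1L, , drop = FALSE]
}

.numericChem <- function(e, type, integer = FALSE) {
  row <- .chemValue(e, type)
  if (is.null(row)) return(if (integer) NA_integer_ else NA_real_)
  v <- row$CHEMICAL_DATA
  if (is.na(v))
    return(if (integer) NA_integer_ else NA_real_)
  if (integer) {
    if (!grepl("^[+-]?[0-9]+$", v))
      stopChebi(sprintf("corrupt chemical datum in row %d: '%s' is not an integer",
                        row$ID, v), "chebi_corrupt_datum")
    as.integer(v)
  } else {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num))
      stopChebi(sprintf("corrupt chemical datum in row %d: '%s' is not numeric",
                        row$ID, v), "chebi_corrupt_datum")
    num
  }
}

## Ordered union with dedup over a key built from selected columns.
.dedup <- function(df, keyCols = names(df)) {
  if (!nrow(df)) return(df)
  key <- do.call(paste, c(lapply(keyCols, function(cn)
    ifelse(is.na(df[[cn]]), "\x01NA", df[[cn]])), sep = "\x02"))
  out <- df[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- scalar getters (primary record; id/parent from the requested) ----

#' Entity getters
#'
#' Accessors of a [ChebiEntity-class].  Scalar fields ([getName()],
#' [getDefinition()], [getStatus()], [getSource()], [getCreatedBy()],
#' [getModifiedOn()], [getStar()], the chemical data and structure
#' getters) are read from the primary record of the merged group, so a
#' deprecated identifier returns the values of the entry that absorbed
#' it.  [getId()] echoes the requested identifier and [getParentId()]
#' its direct parent accession (`NA` for a primary), which together
#' make deprecation detectable.  List-valued getters ([getNames()],
#' [getFormulae()], [getDatabaseAccessions()], [getComments()],
#' [getCompoundOrigins()], [getOutgoings()], [getIncomings()],
#' [getReferences()]) return the ordered, deduplicated union over all
#' group members.  Absent values are typed `NA` (for numeric getters
#' `NA_real_`/`NA_integer_`, distinguishable from a genuine zero).
#'
#' @param x A [ChebiEntity-class].
#' @return See each getter's description.
#' @examples
#' rel <- canonicalMiniRelease()
#' glc <- ChebiEntity("CHEBI:3", rel$dir)
#' getName(glc)
#' getFormula(glc)
#' getOutgoings(glc)
#' @name entity-getters
NULL

#' @describeIn entity-getters Accession text `"CHEBI:<n>"` of the id as
#'   requested (not resolved).
#' @export
setMethod("getId", "ChebiEntity", function(x) chebiAccession(x@requestedId))

#' @describeIn entity-getters Accession of the requested record's
#'   direct parent, or `NA_character_` for a primary entry.
#' @export
setMethod("getParentId", "ChebiEntity", function(x) {
  key <- as.character(x@requestedId)
  if (key %in% names(x@release@parentOf))
    chebiAccession(x@release@parentOf[[key]])
  else NA_character_
})

.primaryField <- function(x, col) {
  row <- .compoundRow(x@release, x@primaryId)
  row[[col]][1L]
}

#' @describeIn entity-getters Preferred name of the primary entry.
#' @export
setMethod("getName", "ChebiEntity", function(x) .primaryField(x, "NAME"))

#' @describeIn entity-getters Curated definition text, or `NA`.
#' @export
setMethod("getDefinition", "ChebiEntity",
          function(x) .primaryField(x, "DEFINITION"))

#' @describeIn entity-getters Single-letter curation status code of
#'   the primary entry.
#' @export
setMethod("getStatus", "ChebiEntity", function(x) .primaryField(x, "STATUS"))

#' @describeIn entity-getters Originating source database text.
#' @export
setMethod("getSource", "ChebiEntity", function(x) .primaryField(x, "SOURCE"))

#' @describeIn entity-getters Curator attribution, or `NA`.
#' @export
setMethod("getCreatedBy", "ChebiEntity",
          function(x) .primaryField(x, "CREATED_BY"))

#' @describeIn entity-getters Last-modified date as a `Date` when the
#'   stored text is an ISO-8601 calendar date; otherwise the raw text
#'   with a warning.
#' @export
setMethod("getModifiedOn", "ChebiEntity", function(x) {
  v <- .primaryField(x, "MODIFIED_ON")
  if (is.na(v)) return(as.Date(NA))
  if (grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", v)) {
    d <- suppressWarnings(as.Date(v))
    if (!is.na(d)) return(d)
  }
  warning(sprintf("unparseable date '%s'; returning raw text", v))
  v
})

#' @describeIn entity-getters Curation star rating (integer).
#' @export
setMethod("getStar", "ChebiEntity", function(x) .primaryField(x, "STAR"))

## ---- list getters (group union) ----

#' @describeIn entity-getters All names and synonyms of the merged
#'   group: data.frame with columns NAME, TYPE, SOURCE, ADAPTED,
#'   LANGUAGE, deduplicated on (NAME, TYPE, LANGUAGE).
#' @export
setMethod("getNames", "ChebiEntity", function(x) {
  rows <- .groupRows(x@release@names, .members(x))
  out <- rows[, c("NAME", "TYPE", "SOURCE", "ADAPTED", "LANGUAGE"),
              drop = FALSE]
  .dedup(out, c("NAME", "TYPE", "LANGUAGE"))
})

#' @describeIn entity-getters Molecular formula text (primary's record
#'   preferred, else the lowest-id member holding one), or `NA`.
#' @export
setMethod("getFormula", "ChebiEntity", function(x) {
  row <- .chemValue(x, "FORMULA")
  if (is.null(row)) NA_character_ else row$CHEMICAL_DATA
})

#' @describeIn entity-getters All formulae of the group with their
#'   sources: data.frame with columns FORMULA, SOURCE.
#' @export
setMethod("getFormulae", "ChebiEntity", function(x) {
  rows <- .groupRows(x@release@chemicalData, .members(x))
  rows <- rows[rows$TYPE == "FORMULA", , drop = FALSE]
  out <- data.frame(FORMULA = rows$CHEMICAL_DATA, SOURCE = rows$SOURCE,
                    stringsAsFactors = FALSE)
  .dedup(out)
})

#' @describeIn entity-getters Molecular mass in unified atomic mass
#'   units, or `NA_real_`.
#' @export
setMethod("getMass", "ChebiEntity",
          function(x) .numericChem(x, "MASS"))

#' @describeIn entity-getters Net charge in elementary charge units as
#'   an integer, or `NA_integer_` (absent is distinct from zero).
#' @export
setMethod("getCharge", "ChebiEntity",
          function(x) .numericChem(x, "CHARGE", integer = TRUE))

#' @describeIn entity-getters Monoisotopic mass, or `NA_real_`.
#' @export
setMethod("getMonoisotopicMass", "ChebiEntity",
          function(x) .numericChem(x, "MONOISOTOPIC MASS"))

#' @describeIn entity-getters Cross-references to external databases:
#'   data.frame with columns SOURCE, TYPE, ACCESSION_NUMBER.
#' @export
setMethod("getDatabaseAccessions", "ChebiEntity", function(x) {
  rows <- .groupRows(x@release@accessions, .members(x))
  out <- rows[, c("SOURCE", "TYPE", "ACCESSION_NUMBER"), drop = FALSE]
  .dedup(out)
})

#' @describeIn entity-getters Curator comments of the group:
#'   data.frame with columns CREATED_ON, DATATYPE, TEXT.
#' @export
setMethod("getComments", "ChebiEntity", function(x) {
  rows <- .groupRows(x@release@comments, .members(x))
  out <- rows[, c("CREATED_ON", "DATATYPE", "TEXT"), drop = FALSE]
  .dedup(out)
})

#' @describeIn entity-getters Biological origins (species, strain,
#'   source) of the group.
#' @export
setMethod("getCompoundOrigins", "ChebiEntity", function(x) {
  rows <- .groupRows(x@release@origins, .members(x))
  out <- rows[, setdiff(names(rows), c("ID", "COMPOUND_ID")), drop = FALSE]
  .dedup(out)
})

## ---- structures ----

#' @describeIn entity-getters Standard InChI text (primary preferred,
#'   then lowest-id member), or `NA_character_`.
#' @export
setMethod("getInchi", "ChebiEntity", function(x) {
  inchis <- x@release@inchis
  for (m in .members(x)) {
    hit <- inchis$INCHI[inchis$CHEBI_ID == m]
    if (length(hit) && !is.na(hit[1L])) return(hit[1L])
  }
  NA_character_
})

.structuresPath <- function(x) {
  path <- x@release@structuresPath
  cfg <- attr(x@release, "cacheConfig")
  if (!is.null(cfg) && (is.na(path) || !file.exists(path)))
    path <- ensureFile("structures", cfg)@localPath
  path
}

.referencesPath <- function(x) {
  path <- x@release@referencesPath
  cfg <- attr(x@release, "cacheConfig")
  if (!is.null(cfg) && (is.na(path) || !file.exists(path)))
    path <- ensureFile("reference", cfg)@localPath
  path
}

.streamedStructure <- function(x, type, dimension = NULL) {
  path <- .structuresPath(x)
  for (m in .members(x)) {
    rec <- streamStructure(m, type, path, dimension = dimension)
    if (!is.null(rec)) return(rec)
  }
  NULL
}

#' @describeIn entity-getters InChIKey, streamed from the structures
#'   file, or `NA_character_`.
#' @export
setMethod("getInchiKey", "ChebiEntity", function(x) {
  rec <- .streamedStructure(x, "InChIKey")
  if (is.null(rec)) NA_character_ else rec$STRUCTURE
})

#' @describeIn entity-getters SMILES string, streamed from the
#'   structures file, or `NA_character_`.
#' @export
setMethod("getSmiles", "ChebiEntity", function(x) {
  rec <- .streamedStructure(x, "SMILES")
  if (is.null(rec)) NA_character_ else rec$STRUCTURE
})

#' @describeIn entity-getters Default 2D MDL molfile text, verbatim
#'   (embedded newlines preserved), or `NA_character_`.
#' @export
setMethod("getMol", "ChebiEntity", function(x) {
  rec <- .streamedStructure(x, "mol", dimension = "2D")
  if (is.null(rec)) NA_character_ else rec$STRUCTURE
})

#' @describeIn entity-getters Writes the molfile to a managed
#'   temporary file (reused per entity) and returns its path, or
#'   `NA_character_` when there is no mol structure.
#' @export
setMethod("getMolFilename", "ChebiEntity", function(x) {
  mol <- getMol(x)
  if (is.na(mol)) return(NA_character_)
  dir <- file.path(tempdir(), "chebir-mol")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, sprintf("chebi_%d_2D.mol", x@primaryId))
  if (!file.exists(path)) {
    con <- file(path, open = "wb")      # exact bytes, no newline appended
    writeBin(charToRaw(enc2utf8(mol)), con)
    close(con)
  }
  path
})

## ---- relations ----

.relationsFor <- function(x, direction) {
  rel <- x@release@relations
  map <- if (direction == "out") x@release@outgoing else x@release@incoming
  idxs <- unlist(map[as.character(.members(x))], use.names = FALSE)
  rows <- rel[idxs, , drop = FALSE]
  targetId <- if (direction == "out") rows$FINAL_ID else rows$INIT_ID
  out <- data.frame(TYPE = rows$TYPE,
                    TARGET = chebiAccession(targetId),
                    STATUS = rows$STATUS, stringsAsFactors = FALSE)
  out <- out[order(out$TYPE, targetId), , drop = FALSE]
  rownames(out) <- NULL
  .dedup(out)
}

#' @describeIn entity-getters Outgoing ontology relations of the
#'   group: data.frame with columns TYPE, TARGET (accession text),
#'   STATUS, ordered by type then target id.
#' @export
setMethod("getOutgoings", "ChebiEntity",
          function(x) .relationsFor(x, "out"))

#' @describeIn entity-getters Incoming ontology relations, same shape
#'   and ordering as [getOutgoings()].
#' @export
setMethod("getIncomings", "ChebiEntity",
          function(x) .relationsFor(x, "in"))

#' @describeIn entity-getters Literature references of the group,
#'   streamed from the references file.
#' @export
setMethod("getReferences", "ChebiEntity", function(x) {
  path <- .referencesPath(x)
  rows <- do.call(rbind, lapply(.members(x), streamReferences,
                                referencesPath = path))
  if (is.null(rows)) rows <- .emptyTable("reference")
  rownames(rows) <- NULL
  .dedup(rows)
})

#' @describeIn ChebiEntity-class Identity, resolution and headline
#'   fields of the entity.
#' @param object A `ChebiEntity`.
#' @export
setMethod("show", "ChebiEntity", function(object) {
  cat(sprintf("ChebiEntity %s", getId(object)))
  if (object@primaryId != object@requestedId)
    cat(sprintf(" (secondary of %s)", chebiAccession(object@primaryId)))
  nm <- getName(object)
  if (!is.na(nm)) cat(sprintf(": %s", nm))
  cat("\n")
  f <- getFormula(object)
  if (!is.na(f)) cat(sprintf("  formula %s\n", f))
  invisible(object)
})
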