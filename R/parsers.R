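## Flat-file parsing and the in-memory release index.
##
## Nine tables are tab-separated with a header row; absent values are
## written as the literal token "null".  Parsing maps "null" to NA,
## accepts LF and CRLF endings, skips malformed rows (wrong column
## count, or garbage in an id column) with a warning -- or raises an
## error in strict mode -- and never fails on an unknown status code.
## The structures and references tables are NOT loaded here: only
## their paths are recorded, and streamStructure()/streamReferences()
## scan them on demand.

.NULL_TOKEN <- "null"

## Read one TSV table into a typed data.frame.
## columnMap, when given, is the character vector of schema column
## names in the order they appear in the file (supporting releases
## whose column order differs from the default layout).
.readTsvTable <- function(path, logicalName, strict = FALSE,
                          columnMap = NULL) {
  .instrLog(logicalName, path)
  schema <- .chebiSchemas[[logicalName]]
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\r$", "", lines)          # accept CRLF
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(list(table = .emptyTable(logicalName), skipped = 0L))

  fileCols <- if (is.null(columnMap)) names(schema$cols) else columnMap
  ncol <- length(fileCols)
  body <- lines[-1L]                       # drop header row
  if (!length(body))
    return(list(table = .emptyTable(logicalName), skipped = 0L))

  ntab <- lengths(regmatches(body, gregexpr("\t", body, fixed = TRUE)))
  good <- ntab + 1L == ncol
  nSkipped <- sum(!good)
  if (nSkipped) {
    msg <- sprintf("%s: skipped %d malformed row(s) (wrong column count)",
                   logicalName, nSkipped)
    if (strict) stopChebi(msg, "chebi_malformed_row") else warning(msg)
  }
  body <- body[good]
  parts <- strsplit(body, "\t", fixed = TRUE)
  ## strsplit drops trailing empty fields; pad them back
  parts <- lapply(parts, function(p) c(p, rep("", ncol - length(p))))
  fields <- lapply(seq_len(ncol), function(i)
    vapply(parts, `[[`, "", i))
  names(fields) <- fileCols
  fields <- fields[names(schema$cols)]     # reorder to schema
  fields <- lapply(fields, function(v) {
    v[v == .NULL_TOKEN] <- NA_character_
    v
  })
  typed <- .typeTable(fields, logicalName)
  if (any(typed$bad)) {
    msg <- sprintf("%s: skipped %d malformed row(s) (non-integer id field)",
                   logicalName, sum(typed$bad))
    if (strict) stopChebi(msg, "chebi_malformed_row") else warning(msg)
  }
  tab <- typed$table[!typed$bad, , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, skipped = nSkipped + sum(typed$bad))
}

## Follow parent links to their fixed point, detecting dangling
## references and cycles.  Returns list(parentOf=, primaryOf=, groupOf=).
.buildParentMaps <- function(compounds) {
  ids <- compounds$ID
  parent <- compounds$PARENT_ID
  names(parent) <- as.character(ids)
  hasParent <- !is.na(parent)
  dangling <- hasParent & !(parent %in% ids)
  if (any(dangling))
    stopChebi(sprintf("dangling parent: compound %s references missing parent %s",
                      paste(ids[dangling], collapse = ","),
                      paste(parent[dangling], collapse = ",")),
              "chebi_dangling_parent")
  primaryOf <- ids
  names(primaryOf) <- as.character(ids)
  for (i in seq_along(ids)) {
    cur <- ids[[i]]
    seen <- cur
    repeat {
      p <- parent[[as.character(cur)]]
      if (is.na(p)) break
      if (p %in% seen)
        stopChebi(sprintf("cyclic parent chain: %s",
                          paste(c(seen, p), collapse = " -> ")),
                  "chebi_cyclic_parents")
      seen <- c(seen, p)
      cur <- p
    }
    primaryOf[[i]] <- cur
  }
  groupOf <- split(ids, primaryOf[as.character(ids)])
  groupOf <- lapply(groupOf, function(g) sort(as.integer(g)))
  parentOf <- parent[hasParent]
  list(parentOf = as.integer(parentOf) |>
         stats::setNames(names(parent)[hasParent]),
       primaryOf = primaryOf, groupOf = groupOf)
}

#' Locate the flat files of a release directory
#'
#' @param dir Directory holding decompressed release files under their
#'   standard names.
#' @return Named character vector of existing file paths, keyed by
#'   logical name.
#' @export
releasePaths <- function(dir) {
  files <- vapply(chebiFileNames(), .chebiFileName, "")
  paths <- file.path(dir, files)
  names(paths) <- chebiFileNames()
  paths[file.exists(paths)]
}

#' Parse a flat-file release into an in-memory index
#'
#' Reads the compounds, names, chemical data, database accession,
#' relation, InChI, comments and compound-origins tables into typed
#' data frames and derives the secondary-to-primary parent map and the
#' merged-group membership map by following parent links to their
#' fixed point.  The structures and references files are not read;
#' their paths are recorded for on-demand streaming.
#'
#' @param paths Named character vector or list mapping logical names
#'   (see [chebiFileNames()]) to local file paths, e.g. from
#'   [releasePaths()].  The compounds table is mandatory; absent
#'   optional tables yield empty maps.
#' @param strict If `TRUE`, malformed rows raise a
#'   `chebi_malformed_row` error instead of a warning.
#' @param columnMap Optional named list: logical name -> character
#'   vector giving the schema column names in the order they appear in
#'   that file, for releases whose column order differs from the
#'   default layout.
#' @param relationDirection `"init_outgoing"` (default) treats a
#'   relation row as INIT_ID --type--> FINAL_ID, i.e. rows with
#'   INIT_ID = e are e's outgoing relations; `"final_outgoing"`
#'   inverts the convention for releases using the opposite
#'   orientation.
#' @return A [ChebiRelease-class] object.
#' @section Errors:
#' `chebi_incomplete_release` if the compounds file is missing;
#' `chebi_dangling_parent` if a PARENT_ID references a nonexistent
#' compound; `chebi_cyclic_parents` if parent links form a cycle.
#' @examples
#' rel <- canonicalMiniRelease()
#' idx <- parseRelease(releasePaths(rel$dir))
#' idx
#' @export
parseRelease <- function(paths, strict = FALSE, columnMap = NULL,
                         relationDirection = c("init_outgoing",
                                               "final_outgoing")) {
  relationDirection <- match.arg(relationDirection)
  paths <- unlist(paths)
  if (!("compounds" %in% names(paths)))
    stopChebi("incomplete release: compounds file is required",
              "chebi_incomplete_release")

  skipped <- integer(0)
  readTab <- function(logicalName) {
    if (logicalName %in% names(paths)) {
      res <- .readTsvTable(paths[[logicalName]], logicalName,
                           strict = strict,
                           columnMap = columnMap[[logicalName]])
      skipped[[logicalName]] <<- res$skipped
      res$table
    } else {
      skipped[[logicalName]] <<- 0L
      .emptyTable(logicalName)
    }
  }

  compounds <- readTab("compounds")
  if (nrow(compounds)) {
    ## enforce the accession invariant; rows violating it are malformed
    okAcc <- !is.na(compounds$CHEBI_ACCESSION) &
      compounds$CHEBI_ACCESSION == chebiAccession(compounds$ID) &
      !is.na(compounds$ID)
    selfPar <- !is.na(compounds$PARENT_ID) &
      compounds$PARENT_ID == compounds$ID
    bad <- !okAcc | selfPar
    if (any(bad)) {
      msg <- sprintf("compounds: skipped %d row(s) violating accession/parent invariants",
                     sum(bad))
      if (strict) stopChebi(msg, "chebi_malformed_row") else warning(msg)
      compounds <- compounds[!bad, , drop = FALSE]
      rownames(compounds) <- NULL
      skipped[["compounds"]] <- skipped[["compounds"]] + sum(bad)
    }
  }

  nms <- readTab("names")
  chem <- readTab("chemical_data")
  acc <- readTab("database_accession")
  rel <- readTab("relation")
  inchi <- readTab("inchi")
  cmt <- readTab("comments")
  org <- readTab("compound_origins")

  if (relationDirection == "final_outgoing" && nrow(rel)) {
    tmp <- rel$INIT_ID
    rel$INIT_ID <- rel$FINAL_ID
    rel$FINAL_ID <- tmp
  }
  if (nrow(rel)) {
    known <- rel$INIT_ID %in% compounds$ID & rel$FINAL_ID %in% compounds$ID
    if (!all(known)) {
      msg <- sprintf("relation: skipped %d row(s) with unknown endpoint",
                     sum(!known))
      if (strict) stopChebi(msg, "chebi_malformed_row") else warning(msg)
      rel <- rel[known, , drop = FALSE]
      rownames(rel) <- NULL
      skipped[["relation"]] <- skipped[["relation"]] + sum(!known)
    }
  }

  maps <- if (nrow(compounds)) .buildParentMaps(compounds)
          else list(parentOf = structure(integer(0), names = character(0)),
                    groupOf = list())

  idx <- seq_len(nrow(rel))
  outgoing <- if (nrow(rel)) split(idx, as.character(rel$INIT_ID)) else list()
  incoming <- if (nrow(rel)) split(idx, as.character(rel$FINAL_ID)) else list()

  new("ChebiRelease",
      compounds = compounds, names = nms, chemicalData = chem,
      accessions = acc, relations = rel, inchis = inchi, comments = cmt,
      origins = org, outgoing = outgoing, incoming = incoming,
      parentOf = maps$parentOf, groupOf = maps$groupOf,
      structuresPath = if ("structures" %in% names(paths))
        paths[["structures"]] else NA_character_,
      referencesPath = if ("reference" %in% names(paths))
        paths[["reference"]] else NA_character_,
      skipped = skipped)
}

#' Resolve a (possibly secondary) id to its primary entry
#'
#' Follows parent links until a record with no parent is reached.
#' Idempotent: resolving a primary id returns it unchanged.
#'
#' @param x A [ChebiRelease-class].
#' @param id Integer compound id present in the release.
#' @return The primary id (integer).
#' @section Errors: `chebi_undefined_id` for an id absent from the
#'   release.
#' @export
setMethod("resolvePrimary", "ChebiRelease", function(x, id) {
  id <- as.integer(id)
  if (!(id %in% x@compounds$ID))
    stopChebi(sprintf("undefined ChEBI id: CHEBI:%d", id),
              "chebi_undefined_id")
  cur <- id
  repeat {
    key <- as.character(cur)
    if (!(key %in% names(x@parentOf))) return(cur)
    cur <- x@parentOf[[key]]
  }
})

#' Members of a merged group
#'
#' @param x A [ChebiRelease-class].
#' @param id Any member id; resolved to its primary first.
#' @return Integer vector of member ids: the primary first, then the
#'   absorbed secondaries in ascending id order.  This ordering defines
#'   the canonical order of all list-valued entity getters.
#' @export
setMethod("groupMembers", "ChebiRelease", function(x, id) {
  p <- resolvePrimary(x, id)
  members <- x@groupOf[[as.character(p)]]
  if (is.null(members)) members <- p
  c(p, sort(setdiff(members, p)))
})

#' @describeIn ChebiRelease-class Summary of table sizes and group
#'   structure.
#' @param object A `ChebiRelease`.
#' @export
setMethod("show", "ChebiRelease", function(object) {
  cat("ChebiRelease index\n")
  cat(sprintf("  compounds: %d (%d secondary, %d merged groups)\n",
              nrow(object@compounds), length(object@parentOf),
              length(object@groupOf)))
  cat(sprintf("  names: %d | chemical data: %d | accessions: %d | relations: %d\n",
              nrow(object@names), nrow(object@chemicalData),
              nrow(object@accessions), nrow(object@relations)))
  cat(sprintf("  inchis: %d | comments: %d | origins: %d\n",
              nrow(object@inchis), nrow(object@comments),
              nrow(object@origins)))
  cat(sprintf("  structures file: %s\n  references file: %s\n",
              ifelse(is.na(object@structuresPath), "<absent>",
                     object@structuresPath),
              ifelse(is.na(object@referencesPath), "<absent>",
                     object@referencesPath)))
  invisible(object)
})
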