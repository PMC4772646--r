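## Internal helpers: file schemas, identifier handling, classed conditions.

## The ten logical files of a flat-file release, with their on-disk names
## and column layouts.  Nine are tab-separated with a header row and the
## literal token "null" for absent values; `structures` is an RFC-4180
## quoted CSV whose STRUCTURE field may span lines (molfile text).
.chebiSchemas <- list(
  compounds = list(
    file = "compounds.tsv", dialect = "tsv",
    cols = c(ID = "integer", STATUS = "character",
             CHEBI_ACCESSION = "character", SOURCE = "character",
             PARENT_ID = "integer", NAME = "character",
             DEFINITION = "character", MODIFIED_ON = "character",
             CREATED_BY = "character", STAR = "integer")),
  names = list(
    file = "names.tsv", dialect = "tsv",
    cols = c(ID = "integer", COMPOUND_ID = "integer", TYPE = "character",
             SOURCE = "character", NAME = "character",
             ADAPTED = "character", LANGUAGE = "character")),
  chemical_data = list(
    file = "chemical_data.tsv", dialect = "tsv",
    cols = c(ID = "integer", COMPOUND_ID = "integer", SOURCE = "character",
             TYPE = "character", CHEMICAL_DATA = "character")),
  database_accession = list(
    file = "database_accession.tsv", dialect = "tsv",
    cols = c(ID = "integer", COMPOUND_ID = "integer", SOURCE = "character",
             TYPE = "character", ACCESSION_NUMBER = "character")),
  relation = list(
    file = "relation.tsv", dialect = "tsv",
    cols = c(ID = "integer", TYPE = "character", INIT_ID = "integer",
             FINAL_ID = "integer", STATUS = "character")),
  inchi = list(
    file = "chebiId_inchi.tsv", dialect = "tsv",
    cols = c(CHEBI_ID = "integer", INCHI = "character")),
  comments = list(
    file = "comments.tsv", dialect = "tsv",
    cols = c(ID = "integer", COMPOUND_ID = "integer",
             CREATED_ON = "character", DATATYPE = "character",
             TEXT = "character")),
  reference = list(
    file = "reference.tsv", dialect = "tsv",
    cols = c(COMPOUND_ID = "integer", REFERENCE_ID = "character",
             REFERENCE_DB_NAME = "character",
             LOCATION_IN_REF = "character",
             REFERENCE_NAME = "character")),
  compound_origins = list(
    file = "compound_origins.tsv", dialect = "tsv",
    cols = c(ID = "integer", COMPOUND_ID = "integer",
             SPECIES_TEXT = "character", SPECIES_ACCESSION = "character",
             COMPONENT_TEXT = "character", STRAIN_TEXT = "character",
             SOURCE_TYPE = "character", SOURCE_ACCESSION = "character",
             COMMENTS = "character")),
  structures = list(
    file = "structures.csv", dialect = "csv",
    cols = c(ID = "integer", COMPOUND_ID = "integer",
             STRUCTURE = "character", TYPE = "character",
             DIMENSION = "character", DEFAULT_STRUCTURE = "character"))
)

#' Logical file names of a flat-file release
#'
#' The ten logical files making up a release, in canonical order.
#'
#' @return Character vector of logical file names.
#' @examples
#' chebiFileNames()
#' @export
chebiFileNames <- function() names(.chebiSchemas)

## On-disk file name for a logical file.
.chebiFileName <- function(logicalName) {
  .chebiSchemas[[.checkLogicalName(logicalName)]]$file
}

.checkLogicalName <- function(logicalName) {
  if (!is.character(logicalName) || length(logicalName) != 1L ||
      !(logicalName %in% names(.chebiSchemas)))
    stop(chebiCondition(
      sprintf("unknown logical file name: %s",
              paste(format(logicalName), collapse = ", ")),
      "chebi_unknown_file"))
  logicalName
}

## Classed error conditions, so callers (and the CLI) can map failures to
## documented behaviour without matching message text.
chebiCondition <- function(msg, class, call = sys.call(-1), ...) {
  structure(
    class = c(class, "chebiError", "error", "condition"),
    list(message = msg, call = call, ...))
}

stopChebi <- function(msg, class, ...) stop(chebiCondition(msg, class, ...))

#' Parse a ChEBI identifier
#'
#' Accepts `"CHEBI:<n>"` (case-insensitively), bare digit strings and
#' whole numbers, all denoting the same compound key.  Anything else is
#' rejected with a `chebi_malformed_id` error rather than silently
#' producing an empty result.
#'
#' @param identifier A length-one character or whole-number identifier.
#' @return The compound key as an integer.
#' @examples
#' parseChebiId("CHEBI:15377")
#' parseChebiId("15377")
#' @export
parseChebiId <- function(identifier) {
  if (length(identifier) != 1L || is.na(identifier))
    stopChebi("malformed identifier: expected a single non-missing value",
              "chebi_malformed_id")
  if (is.numeric(identifier)) {
    if (identifier != trunc(identifier) || identifier < 1)
      stopChebi(sprintf("malformed identifier: %s", format(identifier)),
                "chebi_malformed_id")
    return(as.integer(identifier))
  }
  x <- trimws(as.character(identifier))
  digits <- if (grepl("^[Cc][Hh][Ee][Bb][Ii]:[0-9]+$", x))
    sub("^[^:]*:", "", x)
  else if (grepl("^[0-9]+$", x))
    x
  else
    stopChebi(sprintf("malformed identifier: '%s'", x), "chebi_malformed_id")
  id <- suppressWarnings(as.integer(digits))
  if (is.na(id) || id < 1L)
    stopChebi(sprintf("malformed identifier: '%s'", x), "chebi_malformed_id")
  id
}

## Render a compound key as accession text.
chebiAccession <- function(id) {
  ifelse(is.na(id), NA_character_, paste0("CHEBI:", as.integer(id)))
}

## An empty, correctly typed data.frame for a logical table.
.emptyTable <- function(logicalName) {
  cols <- .chebiSchemas[[logicalName]]$cols
  df <- lapply(cols, function(ty) vector(ty, 0L))
  as.data.frame(df, stringsAsFactors = FALSE)
}

## Coerce character fields (with "null" already mapped to NA) to the
## schema types.  Returns list(table=, bad=logical rows that failed
## integer conversion).
.typeTable <- function(fields, logicalName) {
  cols <- .chebiSchemas[[logicalName]]$cols
  out <- vector("list", length(cols))
  names(out) <- names(cols)
  bad <- rep(FALSE, length(fields[[1L]]))
  for (i in seq_along(cols)) {
    v <- fields[[i]]
    if (cols[[i]] == "integer") {
      iv <- suppressWarnings(as.integer(v))
      bad <- bad | (!is.na(v) & is.na(iv))
      out[[i]] <- iv
    } else {
      out[[i]] <- v
    }
  }
  list(table = as.data.frame(out, stringsAsFactors = FALSE), bad = bad)
}
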