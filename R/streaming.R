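## On-demand streaming of the structures and references tables.
##
## These two files dominate the size of a release, so they are never
## loaded into the index: each lookup scans the file sequentially in
## small fixed-size chunks, keeping only the rows for the requested
## compound.

.STREAM_CHUNK <- 64L

#' Stream one structure record from the structures file
#'
#' Scans the quoted-CSV structures table sequentially and returns the
#' first record for `compoundId` of the requested type, preferring a
#' default structure over non-defaults.  Fields may contain embedded
#' newlines (molfile text) and doubled quotes; at most a fixed chunk of
#' rows is resident at any point during the scan.
#'
#' @param compoundId Integer compound id.
#' @param wantedType Structure notation: `"mol"`, `"SMILES"` or
#'   `"InChIKey"`.
#' @param structuresPath Path of the structures CSV file.
#' @param dimension Optional filter on the DIMENSION column (e.g.
#'   `"2D"`); `NULL` accepts any.
#' @return A one-row data.frame with the structures schema columns, or
#'   `NULL` when the compound has no matching structure.
#' @section Errors: `chebi_corrupt_structures` if the file cannot be
#'   read or parsed.
#' @export
streamStructure <- function(compoundId, wantedType, structuresPath,
                            dimension = NULL) {
  compoundId <- as.integer(compoundId)
  if (is.na(structuresPath) || !file.exists(structuresPath))
    return(NULL)
  .instrLog("structures", structuresPath)
  con <- tryCatch(file(structuresPath, open = "rt", encoding = "UTF-8"),
                  error = function(e)
                    stopChebi(sprintf("corrupt structures file: %s",
                                      conditionMessage(e)),
                              "chebi_corrupt_structures"))
  on.exit(close(con), add = TRUE)
  header <- readLines(con, n = 1L)         # header row: no embedded newlines
  cols <- names(.chebiSchemas$structures$cols)
  matches <- NULL
  repeat {
    chunk <- tryCatch(
      utils::read.csv(con, header = FALSE, nrows = .STREAM_CHUNK,
                      colClasses = "character", comment.char = "",
                      stringsAsFactors = FALSE, na.strings = character(0)),
      error = function(e) {
        if (grepl("no lines available", conditionMessage(e)))
          return(NULL)
        stopChebi(sprintf("corrupt structures file: %s",
                          conditionMessage(e)),
                  "chebi_corrupt_structures")
      })
    if (is.null(chunk) || !nrow(chunk)) break
    if (ncol(chunk) != length(cols))
      stopChebi("corrupt structures file: wrong column count",
                "chebi_corrupt_structures")
    names(chunk) <- cols
    hit <- suppressWarnings(as.integer(chunk$COMPOUND_ID)) == compoundId &
      chunk$TYPE == wantedType
    if (!is.null(dimension)) hit <- hit & chunk$DIMENSION == dimension
    hit[is.na(hit)] <- FALSE
    if (any(hit)) matches <- rbind(matches, chunk[hit, , drop = FALSE])
    if (nrow(chunk) < .STREAM_CHUNK) break
  }
  if (is.null(matches) || !nrow(matches)) return(NULL)
  matches$ID <- as.integer(matches$ID)
  matches$COMPOUND_ID <- as.integer(matches$COMPOUND_ID)
  rownames(matches) <- NULL
  isDefault <- matches$DEFAULT_STRUCTURE %in% c("Y", "YES", "TRUE")
  pick <- if (any(isDefault)) which(isDefault)[1L] else 1L
  matches[pick, , drop = FALSE]
}

#' Stream the literature references of a compound
#'
#' Scans the tab-separated references table sequentially and returns
#' all rows for `compoundId` in file order.  Nothing beyond the result
#' is retained after the call.
#'
#' @param compoundId Integer compound id.
#' @param referencesPath Path of the references TSV file.
#' @return A data.frame with the reference schema columns (zero rows
#'   when the compound has none).
#' @section Errors: `chebi_corrupt_references` if the file cannot be
#'   read.
#' @export
streamReferences <- function(compoundId, referencesPath) {
  compoundId <- as.integer(compoundId)
  if (is.na(referencesPath) || !file.exists(referencesPath))
    return(.emptyTable("reference"))
  .instrLog("reference", referencesPath)
  cols <- .chebiSchemas$reference$cols
  con <- tryCatch(file(referencesPath, open = "rt", encoding = "UTF-8"),
                  error = function(e)
                    stopChebi(sprintf("corrupt references file: %s",
                                      conditionMessage(e)),
                              "chebi_corrupt_references"))
  on.exit(close(con), add = TRUE)
  readLines(con, n = 1L)                   # header
  out <- .emptyTable("reference")
  repeat {
    lines <- readLines(con, n = 512L, warn = FALSE)
    if (!length(lines)) break
    lines <- sub("\r$", "", lines)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    parts <- parts[lengths(parts) == length(cols)]
    if (!length(parts)) next
    keep <- vapply(parts, function(p)
      identical(suppressWarnings(as.integer(p[[1L]])), compoundId), TRUE)
    for (p in parts[keep]) {
      p[p == .NULL_TOKEN] <- NA_character_
      row <- as.data.frame(as.list(p), stringsAsFactors = FALSE)
      names(row) <- names(cols)
      row$COMPOUND_ID <- as.integer(row$COMPOUND_ID)
      out <- rbind(out, row)
    }
  }
  rownames(out) <- NULL
  out
}
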