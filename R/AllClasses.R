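#' @import methods
NULL

#' CacheConfig: where and how release files are cached
#'
#' Configuration for the local flat-file cache.  `baseUrl` may be an
#' `http(s)` or `ftp` location or a plain local directory (used by the
#' test suite as a mock remote).  `maxAge` is the number of days after
#' which a cached file is considered stale and re-fetched.  With
#' `offline = TRUE` no remote access is ever attempted; a missing file
#' then raises a `chebi_offline_miss` error.  The transport and clock
#' are injectable so that fetch behaviour and staleness are
#' deterministically testable.
#'
#' @slot cacheDir Directory holding the decompressed files plus a
#'   sidecar metadata file of retrieval timestamps.
#' @slot baseUrl Remote base location the per-file names are appended to.
#' @slot maxAge Staleness threshold in days (default 30, matching the
#'   monthly release cycle).
#' @slot offline If `TRUE`, never touch the network.
#' @slot transport A `function(url, destfile)` performing one fetch.
#' @slot clock A zero-argument function returning the current `POSIXct`
#'   time.
#' @seealso [cacheConfig()], [ensureFile()], [purgeCache()]
#' @export
setClass("CacheConfig", representation(
  cacheDir = "character",
  baseUrl = "character",
  maxAge = "numeric",
  offline = "logical",
  transport = "function",
  clock = "function"
))

setValidity("CacheConfig", function(object) {
  msgs <- character(0)
  if (length(object@cacheDir) != 1L || is.na(object@cacheDir) ||
      !nzchar(object@cacheDir))
    msgs <- c(msgs, "cacheDir must be a single non-empty path")
  if (length(object@baseUrl) != 1L || is.na(object@baseUrl))
    msgs <- c(msgs, "baseUrl must be a single string")
  if (length(object@maxAge) != 1L || is.na(object@maxAge) ||
      object@maxAge < 0)
    msgs <- c(msgs, "maxAge must be a single non-negative number of days")
  if (length(object@offline) != 1L || is.na(object@offline))
    msgs <- c(msgs, "offline must be TRUE or FALSE")
  if (length(msgs)) msgs else TRUE
})

#' FileRecord: one cached, decompressed flat file
#'
#' Returned by [ensureFile()].  `localPath` always points at a readable,
#' non-empty, decompressed file; `retrievedAt` records when its content
#' was last fetched (or first seen locally).
#'
#' @slot logicalName One of [chebiFileNames()].
#' @slot localPath Path of the decompressed file under the cache dir.
#' @slot retrievedAt `POSIXct` timestamp of retrieval.
#' @slot decompressed `TRUE` if a gzip/zip container was unpacked.
#' @seealso [ensureFile()], [isStale()]
#' @export
setClass("FileRecord", representation(
  logicalName = "character",
  localPath = "character",
  retrievedAt = "POSIXct",
  decompressed = "logical"
))

#' ChebiRelease: the in-memory index of a parsed release
#'
#' Holds the parsed compounds, names, chemical data, database
#' accessions, ontology relations, InChIs, comments and compound
#' origins of one release, together with the secondary-to-primary
#' parent map and the merged-group membership map derived from it.
#'
#' Structure and reference tables are deliberately *not* part of this
#' object: they are large, and are streamed from disk on demand via
#' [streamStructure()] and [streamReferences()].  Only their file paths
#' are retained.
#'
#' @slot compounds,names,chemicalData,accessions,relations,inchis,comments,origins
#'   Typed `data.frame`s, one per parsed table (empty when the file was
#'   absent from the release).
#' @slot outgoing,incoming Named lists mapping a compound id to the row
#'   indices of `relations` in which it is the INIT (outgoing) or FINAL
#'   (incoming) endpoint; every relation row appears exactly once in
#'   each map.
#' @slot parentOf Named integer vector: secondary id -> parent id.
#' @slot groupOf Named list: primary id -> integer vector of all member
#'   ids (the primary plus every record whose parent chain ends at it).
#' @slot structuresPath,referencesPath Paths of the on-disk structures
#'   and references files (`NA` if absent).
#' @slot skipped Named integer vector counting malformed rows skipped
#'   per table.
#' @seealso [parseRelease()], [resolvePrimary()], [ChebiEntity()]
#' @export
setClass("ChebiRelease", representation(
  compounds = "data.frame",
  names = "data.frame",
  chemicalData = "data.frame",
  accessions = "data.frame",
  relations = "data.frame",
  inchis = "data.frame",
  comments = "data.frame",
  origins = "data.frame",
  outgoing = "list",
  incoming = "list",
  parentOf = "integer",
  groupOf = "list",
  structuresPath = "character",
  referencesPath = "character",
  skipped = "integer"
))

setValidity("ChebiRelease", function(object) {
  msgs <- character(0)
  cmp <- object@compounds
  if (nrow(cmp)) {
    if (anyDuplicated(cmp$ID))
      msgs <- c(msgs, "duplicate compound ids")
    ok <- cmp$CHEBI_ACCESSION == chebiAccession(cmp$ID)
    if (!all(ok))
      msgs <- c(msgs, "CHEBI_ACCESSION must equal 'CHEBI:' + ID")
    if (any(!is.na(cmp$PARENT_ID) & cmp$PARENT_ID == cmp$ID))
      msgs <- c(msgs, "a compound may not be its own parent")
  }
  nrel <- nrow(object@relations)
  if (length(unlist(object@outgoing)) != nrel ||
      length(unlist(object@incoming)) != nrel)
    msgs <- c(msgs,
              "each relation must appear exactly once in outgoing and incoming")
  if (length(msgs)) msgs else TRUE
})

#' ChebiEntity: a handle on one chemical entity
#'
#' The primary entry point of the package.  Constructed from a textual
#' identifier (`"CHEBI:<n>"` or bare digits); a secondary (merged)
#' identifier is transparently resolved to its primary entry, and all
#' getters except [getId()] and [getParentId()] read through the merged
#' group, so deprecated identifiers keep returning the full curated
#' record.
#'
#' @slot requestedId The id as given by the caller.
#' @slot primaryId The id after secondary-identifier resolution.
#' @slot release The shared [ChebiRelease-class] index.
#' @seealso [ChebiEntity()], [getName()], [getNames()], [getOutgoings()]
#' @export
setClass("ChebiEntity", representation(
  requestedId = "integer",
  primaryId = "integer",
  release = "ChebiRelease"
))

#' FixtureSpec: parameters of a generated miniature release
#'
#' @slot nPrimary Number of primary (live) compounds.
#' @slot nSecondary Number of secondary (merged) compounds.
#' @slot maxParentChain Maximum parent-chain depth (1 = all secondaries
#'   point directly at a primary).
#' @slot relationDensity Expected number of ontology relations per
#'   primary compound.
#' @slot seed Integer random seed; the same spec and seed always
#'   produce byte-identical output.
#' @slot include Character vector of optional tables to emit (the
#'   compounds table is always emitted).
#' @seealso [fixtureSpec()], [generateFixture()]
#' @export
setClass("FixtureSpec", representation(
  nPrimary = "integer",
  nSecondary = "integer",
  maxParentChain = "integer",
  relationDensity = "numeric",
  seed = "integer",
  include = "character"
))

setValidity("FixtureSpec", function(object) {
  msgs <- character(0)
  if (object@nPrimary < 0L || object@nSecondary < 0L)
    msgs <- c(msgs, "counts must be non-negative")
  if (object@maxParentChain < 1L)
    msgs <- c(msgs, "maxParentChain must be at least 1")
  if (object@relationDensity < 0)
    msgs <- c(msgs, "relationDensity must be non-negative")
  bad <- setdiff(object@include, chebiFileNames())
  if (length(bad))
    msgs <- c(msgs, paste("unknown tables in include:",
                          paste(bad, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})
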