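## Release-file cache: check locally, fetch when missing or stale,
## decompress, and hand a readable local path to the parsers.

.CHEBI_FTP_BASE <-
  "https://ftp.ebi.ac.uk/pub/databases/chebi/Flat_file_tab_delimited"

#' Construct a cache configuration
#'
#' @param cacheDir Directory for cached files; created on first use.
#' @param baseUrl Remote base location.  `http(s)`/`ftp` URLs are
#'   fetched over the network; a local directory path (or `file://`
#'   URL) is copied from, which is how the test suite runs fully
#'   offline.  Defaults to the public ChEBI flat-file area.
#' @param maxAge Days before a cached file counts as stale (default 30;
#'   releases are monthly).
#' @param offline If `TRUE`, never attempt remote access; a cache miss
#'   becomes a `chebi_offline_miss` error.
#' @param transport Fetch function `function(url, destfile)`; the
#'   default dispatches on the URL scheme.  Tests inject an
#'   [instrumentedTransport()] to count remote accesses.
#' @param clock Zero-argument function returning the current time as
#'   `POSIXct`; injectable so staleness is testable.
#' @return A [CacheConfig-class] object.
#' @examples
#' cfg <- cacheConfig(tempfile("cache"), baseUrl = tempdir(), offline = TRUE)
#' @export
cacheConfig <- function(cacheDir,
                        baseUrl = .CHEBI_FTP_BASE,
                        maxAge = 30,
                        offline = FALSE,
                        transport = defaultTransport,
                        clock = Sys.time) {
  new("CacheConfig", cacheDir = as.character(cacheDir),
      baseUrl = as.character(baseUrl), maxAge = as.numeric(maxAge),
      offline = as.logical(offline), transport = transport, clock = clock)
}

#' Default fetch transport
#'
#' Copies `url` to `destfile`.  `http(s)`/`ftp` URLs go through
#' [utils::download.file()]; anything else is treated as a local path
#' (`file://` prefixes are stripped), supporting directory-backed mock
#' remotes.  Raises a `chebi_fetch_failed` error when the source is
#' unavailable.
#'
#' @param url Source location of one file.
#' @param destfile Local path to write to.
#' @return `TRUE` invisibly on success.
#' @export
defaultTransport <- function(url, destfile) {
  if (grepl("^(https?|ftp)://", url)) {
    status <- tryCatch(
      utils::download.file(url, destfile, mode = "wb", quiet = TRUE),
      error = function(e) e, warning = function(w) w)
    if (inherits(status, "condition") || !identical(status, 0L))
      stopChebi(sprintf("fetch failed: %s (%s)", url,
                        if (inherits(status, "condition"))
                          conditionMessage(status) else "non-zero status"),
                "chebi_fetch_failed")
  } else {
    src <- sub("^file://", "", url)
    if (!file.exists(src))
      stopChebi(sprintf("fetch failed: no such file '%s'", src),
                "chebi_fetch_failed")
    if (!file.copy(src, destfile, overwrite = TRUE))
      stopChebi(sprintf("fetch failed: could not copy '%s'", src),
                "chebi_fetch_failed")
  }
  invisible(TRUE)
}

#' Wrap a transport so every attempted fetch is recorded
#'
#' @param inner The transport to delegate to (default
#'   [defaultTransport]).
#' @return A transport function; pass it to [cacheConfig()] and inspect
#'   it with [attemptedUrls()].
#' @examples
#' tr <- instrumentedTransport()
#' attemptedUrls(tr)
#' @export
instrumentedTransport <- function(inner = defaultTransport) {
  log <- new.env(parent = emptyenv())
  log$urls <- character(0)
  fn <- function(url, destfile) {
    log$urls <- c(log$urls, url)
    inner(url, destfile)
  }
  attr(fn, "chebiTransportLog") <- log
  fn
}

#' @rdname instrumentedTransport
#' @param transport A transport created by [instrumentedTransport()].
#' @export
attemptedUrls <- function(transport) {
  log <- attr(transport, "chebiTransportLog")
  if (is.null(log)) stop("not an instrumented transport")
  log$urls
}

## ---- sidecar metadata (retrieval timestamps) ----

.metaPath <- function(cacheDir) file.path(cacheDir, "cache-meta.tsv")

.readCacheMeta <- function(cacheDir) {
  path <- .metaPath(cacheDir)
  if (!file.exists(path)) return(structure(numeric(0), names = character(0)))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) == 2L
  parts <- parts[ok]
  vals <- vapply(parts, function(p) suppressWarnings(as.numeric(p[2L])), 0)
  names(vals) <- vapply(parts, `[[`, "", 1L)
  vals[!is.na(vals)]
}

.writeCacheMeta <- function(cacheDir, meta) {
  tmp <- tempfile("meta", tmpdir = cacheDir)
  writeLines(sprintf("%s\t%.6f", names(meta), unname(meta)), tmp)
  file.rename(tmp, .metaPath(cacheDir))
  invisible(NULL)
}

## ---- decompression ----

## Unpack `src` (recognised by suffix) into `dest`.  A zip with several
## members selects the one whose basename matches `wanted`.
.decompressTo <- function(src, dest, wanted) {
  if (grepl("\\.gz$", src, ignore.case = TRUE)) {
    ## gzfile() silently falls back to plain reading, so check the
    ## gzip magic explicitly before trusting the stream
    magic <- readBin(src, raw(), 2L)
    if (length(magic) < 2L || !identical(magic, as.raw(c(0x1f, 0x8b))))
      stop("not a gzip stream")
    inCon <- gzfile(src, open = "rb")
    on.exit(close(inCon), add = TRUE)
    outCon <- file(dest, open = "wb")
    on.exit(close(outCon), add = TRUE)
    ## a truncated stream surfaces as a warning; treat it as corrupt
    withCallingHandlers(
      repeat {
        chunk <- readBin(inCon, raw(), n = 1048576L)
        if (!length(chunk)) break
        writeBin(chunk, outCon)
      },
      warning = function(w) stop(conditionMessage(w)))
  } else if (grepl("\\.zip$", src, ignore.case = TRUE)) {
    members <- utils::unzip(src, list = TRUE)$Name
    pick <- members[basename(members) == wanted]
    if (!length(pick)) pick <- members[1L]
    if (!length(pick)) stop("empty zip archive")
    exdir <- tempfile("unzip", tmpdir = dirname(dest))
    dir.create(exdir)
    on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
    utils::unzip(src, files = pick[1L], exdir = exdir, junkpaths = TRUE)
    if (!file.rename(file.path(exdir, basename(pick[1L])), dest))
      file.copy(file.path(exdir, basename(pick[1L])), dest, overwrite = TRUE)
  } else {
    if (!file.copy(src, dest, overwrite = TRUE)) stop("copy failed")
  }
  invisible(NULL)
}

.fileRecord <- function(logicalName, localPath, retrievedAt,
                        decompressed = FALSE) {
  new("FileRecord", logicalName = logicalName, localPath = localPath,
      retrievedAt = as.POSIXct(retrievedAt), decompressed = decompressed)
}

#' Ensure a release file is available locally
#'
#' Implements the check-fetch-parse flow: if a fresh decompressed copy
#' of the requested logical file exists under the cache directory it is
#' returned with no remote access; otherwise (missing, or older than
#' `maxAge` days) the file is fetched from `baseUrl`, trying the
#' gzipped (`.gz`), zipped (`.zip`) and plain names in that order,
#' unpacked, and atomically moved into place, so a failed download
#' never leaves a truncated file behind.
#'
#' @param logicalName One of [chebiFileNames()].
#' @param config A [cacheConfig()].
#' @return A [FileRecord-class] whose `localPath` is readable, non-empty
#'   and decompressed.
#' @section Errors:
#' `chebi_offline_miss` when `offline = TRUE` and there is no local
#' copy; `chebi_fetch_failed` when every remote candidate fails;
#' `chebi_corrupt_download` when decompression fails or yields an empty
#' file (the partial file is removed).
#' @examples
#' fx <- generateFixture(fixtureSpec(nPrimary = 2, nSecondary = 0))
#' cfg <- cacheConfig(tempfile("cache"), baseUrl = fx$dir)
#' rec <- ensureFile("compounds", cfg)
#' @export
ensureFile <- function(logicalName, config) {
  .checkLogicalName(logicalName)
  stopifnot(is(config, "CacheConfig"))
  fname <- .chebiFileName(logicalName)
  if (!dir.exists(config@cacheDir))
    dir.create(config@cacheDir, recursive = TRUE)
  localPath <- file.path(config@cacheDir, fname)
  now <- config@clock()
  meta <- .readCacheMeta(config@cacheDir)

  haveLocal <- file.exists(localPath) && file.size(localPath) > 0L
  retrievedAt <- if (logicalName %in% names(meta))
    as.POSIXct(meta[[logicalName]], origin = "1970-01-01", tz = "UTC")
  else if (haveLocal)
    file.mtime(localPath)
  else
    NULL

  if (haveLocal) {
    rec <- .fileRecord(logicalName, localPath, retrievedAt)
    if (!isStale(rec, now, config@maxAge) || config@offline)
      return(rec)
  } else if (config@offline) {
    stopChebi(sprintf("offline cache miss: no local copy of '%s' (%s)",
                      logicalName, fname),
              "chebi_offline_miss")
  }

  ## fetch: try compressed containers first, then the plain file
  candidates <- paste0(fname, c(".gz", ".zip", ""))
  sep <- if (grepl("/$", config@baseUrl)) "" else "/"
  fetched <- NULL
  failures <- character(0)
  for (cand in candidates) {
    url <- paste0(config@baseUrl, sep, cand)
    part <- tempfile("fetch", tmpdir = config@cacheDir,
                     fileext = paste0(".", cand, ".part"))
    res <- tryCatch({
      config@transport(url, part)
      part
    }, error = function(e) {
      unlink(part)
      failures <<- c(failures, conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      fetched <- res
      fetchedName <- cand
      break
    }
  }
  if (is.null(fetched))
    stopChebi(sprintf("fetch failed for '%s' from %s: %s", logicalName,
                      config@baseUrl, paste(failures, collapse = "; ")),
              "chebi_fetch_failed")
  on.exit(unlink(fetched), add = TRUE)

  ## decompress to a second temp file, then rename atomically
  plain <- tempfile("plain", tmpdir = config@cacheDir, fileext = ".part")
  ok <- tryCatch({
    ## strip the trailing ".part" we appended so the suffix check sees
    ## the container extension
    src <- sub("\\.part$", "", fetched)
    file.rename(fetched, src)
    fetched <- src
    .decompressTo(src, plain, fname)
    TRUE
  }, error = function(e) e)
  if (inherits(ok, "condition") || !file.exists(plain) ||
      file.size(plain) == 0L) {
    unlink(plain)
    stopChebi(sprintf("corrupt download for '%s': %s", logicalName,
                      if (inherits(ok, "condition")) conditionMessage(ok)
                      else "empty result"),
              "chebi_corrupt_download")
  }
  file.rename(plain, localPath)

  now <- config@clock()
  meta[[logicalName]] <- as.numeric(now)
  .writeCacheMeta(config@cacheDir, meta)
  .fileRecord(logicalName, localPath, now,
              decompressed = grepl("\\.(gz|zip)$", fetchedName))
}

#' Is a cached file stale?
#'
#' Pure function of its arguments: a record is stale when strictly more
#' than `maxAge` days have elapsed between its retrieval and `now`.
#'
#' @param record A [FileRecord-class].
#' @param now Current time (`POSIXct`).
#' @param maxAge Maximum age in days.
#' @return `TRUE` or `FALSE`.
#' @export
setMethod("isStale", signature(record = "FileRecord"),
  function(record, now, maxAge) {
    age <- as.numeric(difftime(as.POSIXct(now), record@retrievedAt,
                               units = "days"))
    stopifnot(age >= -1e-9)  # retrievedAt must not lie in the future
    age > maxAge
  })

#' Empty the cache
#'
#' Removes every managed file (the ten decompressed release files, the
#' metadata sidecar and any leftover partial downloads) from the cache
#' directory.  A missing cache directory is a no-op.
#'
#' @param config A [cacheConfig()].
#' @return The number of managed release files removed (the sidecar and
#'   partials are not counted).
#' @export
purgeCache <- function(config) {
  stopifnot(is(config, "CacheConfig"))
  if (!dir.exists(config@cacheDir)) return(0L)
  managed <- file.path(config@cacheDir,
                       vapply(chebiFileNames(), .chebiFileName, ""))
  present <- managed[file.exists(managed)]
  unlink(present)
  unlink(.metaPath(config@cacheDir))
  unlink(list.files(config@cacheDir, pattern = "\\.part$",
                    full.names = TRUE))
  length(present)
}

#' @describeIn CacheConfig-class Compact summary of the cache location
#'   and policy.
#' @param object A `CacheConfig`.
#' @export
setMethod("show", "CacheConfig", function(object) {
  cat("CacheConfig\n",
      "  cacheDir: ", object@cacheDir, "\n",
      "  baseUrl:  ", object@baseUrl, "\n",
      "  maxAge:   ", object@maxAge, " days\n",
      "  offline:  ", object@offline, "\n", sep = "")
  invisible(object)
})

#' @describeIn FileRecord-class One-line summary of a cached file.
#' @param object A `FileRecord`.
#' @export
setMethod("show", "FileRecord", function(object) {
  cat(sprintf("FileRecord '%s' at %s (retrieved %s)\n", object@logicalName,
              object@localPath, format(object@retrievedAt)))
  invisible(object)
})
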