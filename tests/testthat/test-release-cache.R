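## Cache lifecycle: check locally, fetch when missing or stale,
## decompress transparently, never leave partial files behind.

mockRemote <- function(seed = 3L) {
  generateFixture(fixtureSpec(nPrimary = 4L, nSecondary = 2L,
                              seed = seed),
                  tempfile("remote"))
}

test_that("cold cache fetches once, fresh cache not at all, and the
           delivered file is byte-identical to the remote", {
  fx <- mockRemote()
  tr <- instrumentedTransport()
  clock <- makeClock()
  cfg <- cacheConfig(tempfile("cache"), baseUrl = fx$dir,
                     transport = tr, clock = clock$now)

  rec <- ensureFile("compounds", cfg)
  expect_s4_class(rec, "FileRecord")
  expect_length(attemptedUrls(tr), 1L)
  expect_true(rec@decompressed)  # the .gz candidate is preferred
  expect_identical(
    readBin(rec@localPath, raw(), file.size(rec@localPath)),
    readBin(file.path(fx$dir, "compounds.tsv"),
            raw(), file.size(file.path(fx$dir, "compounds.tsv"))))

  ## cache-hit purity: a second call performs zero remote accesses
  rec2 <- ensureFile("compounds", cfg)
  expect_length(attemptedUrls(tr), 1L)
  expect_identical(rec2@localPath, rec@localPath)
})

test_that("advancing the clock past maxAge triggers exactly one
           refetch", {
  fx <- mockRemote()
  tr <- instrumentedTransport()
  clock <- makeClock()
  cfg <- cacheConfig(tempfile("cache"), baseUrl = fx$dir,
                     transport = tr, clock = clock$now, maxAge = 30)
  ensureFile("names", cfg)
  clock$advanceDays(29)
  ensureFile("names", cfg)
  expect_length(attemptedUrls(tr), 1L)   # still fresh
  clock$advanceDays(2)
  ensureFile("names", cfg)
  expect_length(attemptedUrls(tr), 2L)   # one refetch
  ensureFile("names", cfg)
  expect_length(attemptedUrls(tr), 2L)   # fresh again
})

test_that("staleness is a pure, strict-inequality function of age", {
  t0 <- as.POSIXct("2026-01-01", tz = "UTC")
  rec <- new("FileRecord", logicalName = "compounds",
             localPath = "x", retrievedAt = t0, decompressed = FALSE)
  expect_false(isStale(rec, t0, 30))                       # zero age
  expect_false(isStale(rec, t0 + 30 * 86400, 30))          # boundary
  expect_true(isStale(rec, t0 + 31 * 86400, 30))
  expect_true(isStale(rec, t0 + 30 * 86400 + 1, 30))
})

test_that("offline mode never touches the transport and reports a
           cache miss for absent files", {
  fx <- mockRemote()
  tr <- instrumentedTransport()
  cfg <- cacheConfig(tempfile("cache"), baseUrl = fx$dir,
                     offline = TRUE, transport = tr)
  expect_error(ensureFile("names", cfg), class = "chebi_offline_miss")
  expect_length(attemptedUrls(tr), 0L)

  ## a stale-but-present file is still served offline, with no fetch
  clock <- makeClock()
  cfg2 <- cacheConfig(tempfile("cache"), baseUrl = fx$dir,
                      transport = tr, clock = clock$now)
  ensureFile("names", cfg2)
  clock$advanceDays(90)
  cfgOff <- cacheConfig(cfg2@cacheDir, baseUrl = fx$dir, offline = TRUE,
                        transport = tr, clock = clock$now)
  rec <- ensureFile("names", cfgOff)
  expect_true(file.exists(rec@localPath))
  expect_length(attemptedUrls(tr), 1L)
})

test_that("a failed or truncated download leaves no partial file and
           preserves any previous valid copy", {
  fx <- mockRemote()
  partialTransport <- function(url, destfile) {
    writeBin(as.raw(1:16), destfile)
    stop("connection reset mid-transfer")
  }
  cfg <- cacheConfig(tempfile("cache"), baseUrl = fx$dir,
                     transport = partialTransport)
  expect_error(ensureFile("compounds", cfg),
               class = "chebi_fetch_failed")
  expect_false(file.exists(file.path(cfg@cacheDir, "compounds.tsv")))
  expect_length(list.files(cfg@cacheDir, pattern = "\\.part$"), 0L)

  ## previous valid copy survives a later failed refresh
  clock <- makeClock()
  cfg2 <- cacheConfig(tempfile("cache"), baseUrl = fx$dir,
                      clock = clock$now)
  good <- readBin(ensureFile("compounds", cfg2)@localPath, raw(), 1e6)
  clock$advanceDays(60)
  cfgBad <- cacheConfig(cfg2@cacheDir, baseUrl = fx$dir,
                        transport = partialTransport, clock = clock$now)
  expect_error(ensureFile("compounds", cfgBad),
               class = "chebi_fetch_failed")
  expect_identical(
    readBin(file.path(cfg2@cacheDir, "compounds.tsv"), raw(), 1e6),
    good)
})

test_that("a download that succeeds but is not valid gzip is reported
           as corrupt and removed", {
  garbageTransport <- function(url, destfile) {
    if (!grepl("\\.gz$", url)) stop("only serving gz")
    writeBin(as.raw(rep(7L, 64L)), destfile)
  }
  cfg <- cacheConfig(tempfile("cache"), baseUrl = "mock",
                     transport = garbageTransport)
  expect_error(ensureFile("compounds", cfg),
               class = "chebi_corrupt_download")
  expect_false(file.exists(file.path(cfg@cacheDir, "compounds.tsv")))
})

test_that("zip containers are unpacked, selecting the member matching
           the logical file", {
  fx <- mockRemote()
  remote <- tempfile("zipremote")
  dir.create(remote)
  ## zip holding two members; the names member must be selected
  writeStoredZip(c(file.path(fx$dir, "compounds.tsv"),
                   file.path(fx$dir, "names.tsv")),
                 file.path(remote, "names.tsv.zip"))
  cfg <- cacheConfig(tempfile("cache"), baseUrl = remote)
  rec <- ensureFile("names", cfg)
  expect_true(rec@decompressed)
  expect_identical(readBin(rec@localPath, raw(), 1e6),
                   readBin(file.path(fx$dir, "names.tsv"), raw(), 1e6))
})

test_that("purge empties the cache and forces a refetch", {
  fx <- mockRemote()
  tr <- instrumentedTransport()
  cfg <- cacheConfig(tempfile("cache"), baseUrl = fx$dir,
                     transport = tr)
  expect_identical(purgeCache(cfg), 0L)   # missing dir is a no-op
  for (nm in c("compounds", "names", "relation")) ensureFile(nm, cfg)
  expect_length(attemptedUrls(tr), 3L)
  expect_identical(purgeCache(cfg), 3L)
  expect_length(list.files(cfg@cacheDir,
                           pattern = "\\.(tsv|csv)$"), 0L)
  ensureFile("compounds", cfg)
  expect_length(attemptedUrls(tr), 4L)
})

test_that("unknown logical names are rejected", {
  cfg <- cacheConfig(tempfile("cache"), baseUrl = "mock")
  expect_error(ensureFile("nonsense", cfg),
               class = "chebi_unknown_file")
})
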