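## Shared helpers: the getter registry used to compare entities against
## manifests (and against each other), an injectable clock, and a
## minimal stored-ZIP writer for container tests.

## All entity getters, keyed by the manifest field they correspond to.
## modified_on is compared as raw text (the manifest stores the stored
## form; getModifiedOn parses ISO dates to Date).
entityGetters <- function() list(
  id = getId, parent_id = getParentId, name = getName,
  definition = getDefinition, status = getStatus, source = getSource,
  created_by = getCreatedBy, star = getStar, names = getNames,
  formula = getFormula, formulae = getFormulae, mass = getMass,
  charge = getCharge, monoisotopic_mass = getMonoisotopicMass,
  accessions = getDatabaseAccessions, comments = getComments,
  origins = getCompoundOrigins, inchi = getInchi,
  inchikey = getInchiKey, smiles = getSmiles, mol = getMol,
  outgoings = getOutgoings, incomings = getIncomings,
  references = getReferences)

## Getters whose value is defined per requested record, not per merged
## group (excluded from group-equivalence checks).
identityGetters <- c("id", "parent_id")

sameValue <- function(got, want) {
  if (is.null(want)) want <- NA_character_
  if (is.data.frame(want)) rownames(want) <- NULL
  if (is.data.frame(got)) rownames(got) <- NULL
  identical(got, want) ||
    (length(got) == 1L && length(want) == 1L &&
       is.na(got) && is.na(want)) ||
    isTRUE(all.equal(got, want, check.attributes = FALSE))
}

## Compare every getter of every entity in a fixture to its manifest
## entry; returns a character vector of mismatch descriptions.
compareFixtureEntities <- function(fx) {
  idx <- loadRelease(fx$dir)
  getters <- entityGetters()
  bad <- character(0)
  for (key in names(fx$manifest$entities)) {
    e <- ChebiEntity(key, idx)
    exp <- fx$manifest$entities[[key]]
    for (g in names(getters)) {
      if (!sameValue(getters[[g]](e), exp[[g]]))
        bad <- c(bad, paste(key, g))
    }
  }
  bad
}

## A mutable clock: advanceClock() moves it forward by seconds.
makeClock <- function(start = as.POSIXct("2026-01-01", tz = "UTC")) {
  env <- new.env(parent = emptyenv())
  env$t <- start
  list(now = function() env$t,
       advanceDays = function(d) env$t <- env$t + d * 86400)
}

## ---- minimal stored (uncompressed) ZIP writer ----
## Only what utils::unzip needs: local file headers, central directory,
## end-of-central-directory, with a correct CRC-32.

.crc32Table <- local({
  poly <- -306674912L  # 0xEDB88320 as signed 32-bit
  sapply(0:255, function(n) {
    c <- as.integer(n)
    for (k in 1:8) {
      lsb <- bitwAnd(c, 1L)
      c <- bitwShiftR(bitwAnd(c, -2L), 1L)
      ## logical shift: clear the sign-propagated high bit
      c <- bitwAnd(c, 2147483647L)
      if (lsb) c <- bitwXor(c, poly)
    }
    c
  })
})

crc32 <- function(bytes) {
  c <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(c, b), 255L)
    c <- bitwXor(bitwAnd(bitwShiftR(c, 8L), 16777215L),
                 .crc32Table[[idx + 1L]])
  }
  bitwXor(c, -1L)
}

.le <- function(value, nBytes) {
  ## little-endian unsigned rendering of a (signed 32-bit) value
  v <- as.numeric(value)
  if (v < 0) v <- v + 2^32
  raw <- integer(nBytes)
  for (i in seq_len(nBytes)) {
    raw[[i]] <- v %% 256
    v <- v %/% 256
  }
  as.raw(raw)
}

writeStoredZip <- function(files, zipPath) {
  out <- raw(0)
  central <- raw(0)
  offsets <- integer(length(files))
  for (i in seq_along(files)) {
    name <- charToRaw(basename(files[[i]]))
    data <- readBin(files[[i]], raw(), file.size(files[[i]]))
    crc <- crc32(data)
    offsets[[i]] <- length(out)
    local <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), .le(20, 2), .le(0, 2),
               .le(0, 2), .le(0, 2), .le(0, 2), .le(crc, 4),
               .le(length(data), 4), .le(length(data), 4),
               .le(length(name), 2), .le(0, 2), name, data)
    out <- c(out, local)
    central <- c(central, as.raw(c(0x50, 0x4b, 0x01, 0x02)),
                 .le(20, 2), .le(20, 2), .le(0, 2), .le(0, 2), .le(0, 2),
                 .le(0, 2), .le(crc, 4), .le(length(data), 4),
                 .le(length(data), 4), .le(length(name), 2), .le(0, 2),
                 .le(0, 2), .le(0, 2), .le(0, 2), .le(0, 4),
                 .le(offsets[[i]], 4), name)
  }
  cdStart <- length(out)
  out <- c(out, central, as.raw(c(0x50, 0x4b, 0x05, 0x06)), .le(0, 2),
           .le(0, 2), .le(length(files), 2), .le(length(files), 2),
           .le(length(central), 4), .le(cdStart, 4), .le(0, 2))
  writeBin(out, zipPath)
  invisible(zipPath)
}
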