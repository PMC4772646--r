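## The ChebiEntity getter surface: identifier normalisation, merged
## group semantics, chemical data, structures and relations.

canonical <- canonicalMiniRelease()

test_that("identifier forms normalise to the same entity and bad input
           is rejected", {
  a <- ChebiEntity("CHEBI:1", canonical$dir)
  b <- ChebiEntity("1", canonical$dir)
  d <- ChebiEntity(1L, canonical$dir)
  e <- ChebiEntity("chebi:1", canonical$dir)
  expect_identical(a@primaryId, b@primaryId)
  expect_identical(a@primaryId, d@primaryId)
  expect_identical(a@primaryId, e@primaryId)
  expect_error(ChebiEntity("CHEBI:999999", canonical$dir),
               class = "chebi_undefined_id")
  expect_error(ChebiEntity("glucose", canonical$dir),
               class = "chebi_malformed_id")
  expect_error(ChebiEntity("CHEBI:", canonical$dir),
               class = "chebi_malformed_id")
  expect_error(ChebiEntity("0", canonical$dir),
               class = "chebi_malformed_id")
})

test_that("a secondary id resolves to its parent but keeps its own
           identity visible", {
  sec <- ChebiEntity("CHEBI:2", canonical$dir)
  expect_identical(getId(sec), "CHEBI:2")
  expect_identical(getParentId(sec), "CHEBI:1")
  expect_identical(getName(sec), "water")      # the primary's name
  prim <- ChebiEntity("CHEBI:1", canonical$dir)
  expect_identical(getParentId(prim), NA_character_)
})

test_that("getNames unions the merged group, primary first, with
           duplicates removed", {
  sec <- ChebiEntity("CHEBI:2", canonical$dir)
  nms <- getNames(sec)
  expect_identical(nms$NAME, c("H2O", "WATER"))  # primary's row first
  prim <- ChebiEntity("CHEBI:1", canonical$dir)
  expect_identical(getNames(prim), nms)

  ## duplicate synonym across primary and secondary is returned once
  fx <- generateFixture(fixtureSpec(nPrimary = 6L, nSecondary = 3L,
                                    seed = 19L))
  idx <- loadRelease(fx$dir)
  secId <- names(fx$manifest$parentOf)[1L]
  e <- ChebiEntity(secId, idx)
  shared <- getNames(e)$NAME == "shared synonym"
  expect_identical(sum(shared), 1L)
})

test_that("chemical data getters distinguish absence from zero and
           parse signed values", {
  glc <- ChebiEntity("CHEBI:3", canonical$dir)
  expect_identical(getFormula(glc), "C6H12O6")
  expect_identical(getCharge(glc), 0L)
  expect_identical(getMass(glc), 180.15588)
  expect_identical(getMonoisotopicMass(glc), NA_real_)  # absent, typed

  ald <- ChebiEntity("CHEBI:4", canonical$dir)
  expect_identical(getCharge(ald), NA_integer_)  # absent != 0

  ## signed charges over the generated range parse exactly
  fx <- generateFixture(fixtureSpec(nPrimary = 15L, nSecondary = 0L,
                                    seed = 29L))
  idx <- loadRelease(fx$dir)
  chem <- fx$manifest$tables$chemical_data
  chg <- chem[chem$TYPE == "CHARGE", ]
  expect_true(any(as.integer(chg$CHEMICAL_DATA) < 0L))
  for (i in seq_len(nrow(chg))) {
    e <- ChebiEntity(chg$COMPOUND_ID[[i]], idx)
    expect_identical(getCharge(e), as.integer(chg$CHEMICAL_DATA[[i]]))
  }
})

test_that("a non-numeric token where a number is required is reported
           as a corrupt datum naming the row", {
  tabs <- chebir:::.canonicalTables()
  tabs$chemical_data$CHEMICAL_DATA[2L] <- "eighteen"   # MASS row id 2
  dir <- tempfile("corrupt")
  writeReleaseFiles(tabs, dir)
  e <- ChebiEntity("CHEBI:1", loadRelease(dir))
  err <- tryCatch(getMass(e), error = function(e) e)
  expect_s3_class(err, "chebi_corrupt_datum")
  expect_match(conditionMessage(err), "row 2")
})

test_that("structure getters stream from disk: InChI, InChIKey,
           SMILES, molfile and the molfile round-trips through
           getMolFilename", {
  w <- ChebiEntity("CHEBI:1", canonical$dir)
  expect_identical(getInchi(w), "InChI=1S/H2O/h1H2")
  expect_identical(getInchiKey(w), "XLYOFNOQVPJJNP-UHFFFAOYSA-N")
  expect_identical(getSmiles(w), NA_character_)
  mol <- getMol(w)
  expect_identical(length(strsplit(mol, "\n")[[1L]]), 10L)
  expect_match(mol, "^water\n")
  expect_match(mol, "M  END$")

  path <- getMolFilename(w)
  expect_identical(rawToChar(readBin(path, raw(), file.size(path))),
                   mol)
  expect_identical(getMolFilename(w), path)  # reused, not rewritten

  ald <- ChebiEntity("CHEBI:4", canonical$dir)
  expect_identical(getMol(ald), NA_character_)
  expect_identical(getMolFilename(ald), NA_character_)
  expect_identical(getInchi(ald), NA_character_)
})

test_that("outgoing and incoming relations are dual and ordered", {
  glc <- ChebiEntity("CHEBI:3", canonical$dir)
  ald <- ChebiEntity("CHEBI:4", canonical$dir)
  out <- getOutgoings(glc)
  expect_identical(out$TYPE, "is_a")
  expect_identical(out$TARGET, "CHEBI:4")
  inc <- getIncomings(ald)
  expect_identical(inc$TYPE, "is_a")
  expect_identical(inc$TARGET, "CHEBI:3")
  expect_identical(nrow(getIncomings(glc)), 0L)
  expect_identical(nrow(getOutgoings(ald)), 0L)
})

test_that("group equivalence: every getter except id/parent agrees
           between a secondary and its primary, including deep
           chains", {
  fx <- generateFixture(fixtureSpec(nPrimary = 8L, nSecondary = 5L,
                                    maxParentChain = 3L, seed = 37L))
  idx <- loadRelease(fx$dir)
  getters <- entityGetters()
  po <- fx$manifest$parentOf
  depth <- function(id) {
    d <- 0L; cur <- as.character(id)
    while (cur %in% names(po)) {cur <- as.character(po[[cur]]); d <- d + 1L}
    d
  }
  expect_gte(max(vapply(names(po), depth, 0L)), 2L)
  for (s in names(po)) {
    es <- ChebiEntity(s, idx)
    ep <- ChebiEntity(es@primaryId, idx)
    for (g in setdiff(names(getters), identityGetters)) {
      expect_true(sameValue(getters[[g]](es), getters[[g]](ep)),
                  info = paste("secondary", s, "getter", g))
    }
  }
})

test_that("constructing an entity and reading scalar fields never
           opens the structures or references files", {
  fx <- generateFixture(fixtureSpec(nPrimary = 6L, nSecondary = 2L,
                                    seed = 41L))
  idx <- loadRelease(fx$dir)
  resetFileOpenLog()
  e <- ChebiEntity(fx$manifest$tables$compounds$ID[[1L]], idx)
  getName(e); getCharge(e); getNames(e); getOutgoings(e); getInchi(e)
  expect_length(grep("^(structures|reference):", fileOpenLog()), 0L)
  getMol(e)
  getReferences(e)
  expect_gt(length(grep("^(structures|reference):", fileOpenLog())), 0L)
})

test_that("list getters return identical orderings across repeated
           calls and fresh parses", {
  fx <- generateFixture(fixtureSpec(nPrimary = 10L, nSecondary = 4L,
                                    seed = 43L))
  idx1 <- parseRelease(releasePaths(fx$dir))
  idx2 <- parseRelease(releasePaths(fx$dir))
  for (key in names(fx$manifest$entities)[1:5]) {
    e1 <- ChebiEntity(key, idx1)
    e2 <- ChebiEntity(key, idx2)
    expect_identical(getNames(e1), getNames(e2))
    expect_identical(getOutgoings(e1), getOutgoings(e2))
    expect_identical(getDatabaseAccessions(e1),
                     getDatabaseAccessions(e2))
  }
})

test_that("getModifiedOn parses ISO dates and falls back to raw text
           with a warning", {
  w <- ChebiEntity("CHEBI:1", canonical$dir)
  expect_identical(getModifiedOn(w), as.Date("2016-01-15"))
  tabs <- chebir:::.canonicalTables()
  tabs$compounds$MODIFIED_ON[1L] <- "Jan 2016"
  dir <- tempfile("rawdate")
  writeReleaseFiles(tabs, dir)
  e <- ChebiEntity("CHEBI:1", loadRelease(dir))
  expect_warning(v <- getModifiedOn(e), "unparseable")
  expect_identical(v, "Jan 2016")
})
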