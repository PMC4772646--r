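## Flat-file dialects, the release index, parent resolution and the
## streamed structures/references readers.

.slotForTable <- c(
  compounds = "compounds", names = "names",
  chemical_data = "chemicalData", database_accession = "accessions",
  relation = "relations", inchi = "inchis", comments = "comments",
  compound_origins = "origins")

test_that("a header-only compounds file parses to an empty index", {
  dir <- tempfile("empty")
  writeReleaseFiles(list(compounds = chebir:::.emptyTable("compounds")),
                    dir)
  idx <- parseRelease(releasePaths(dir))
  expect_identical(nrow(idx@compounds), 0L)
  expect_length(idx@groupOf, 0L)
})

test_that("a missing compounds file is an incomplete release", {
  expect_error(parseRelease(list(names = "whatever")),
               class = "chebi_incomplete_release")
})

test_that("a seeded fixture round-trips through the parser field for
           field, in strict mode with zero warnings", {
  fx <- generateFixture(fixtureSpec(nPrimary = 10L, nSecondary = 5L,
                                    seed = 17L))
  expect_no_warning(idx <- parseRelease(releasePaths(fx$dir),
                                        strict = TRUE))
  for (nm in names(.slotForTable))
    expect_identical(slot(idx, .slotForTable[[nm]]),
                     fx$manifest$tables[[nm]], info = nm)
  expect_identical(idx@parentOf, fx$manifest$parentOf)
  expect_identical(idx@groupOf, fx$manifest$groupOf)
})

test_that("the literal token 'null' reads back as NA, never as text", {
  fx <- generateFixture(fixtureSpec(nPrimary = 8L, nSecondary = 4L,
                                    seed = 23L))
  raw <- readLines(file.path(fx$dir, "compounds.tsv"))
  expect_true(any(grepl("\tnull", raw)))   # sentinels were emitted
  idx <- parseRelease(releasePaths(fx$dir))
  expect_false(any(idx@compounds == "null", na.rm = TRUE))
  expect_true(anyNA(idx@compounds$NAME) || anyNA(idx@compounds$DEFINITION))
})

test_that("parent chains resolve to their primary and groups contain
           the whole chain", {
  tabs <- list(compounds = data.frame(
    ID = c(1L, 3L, 5L), STATUS = "C",
    CHEBI_ACCESSION = paste0("CHEBI:", c(1L, 3L, 5L)), SOURCE = "ChEBI",
    PARENT_ID = c(NA_integer_, 1L, 3L), NAME = c("primary", NA, NA),
    DEFINITION = NA_character_, MODIFIED_ON = "2020-01-01",
    CREATED_BY = NA_character_, STAR = 3L, stringsAsFactors = FALSE))
  dir <- tempfile("chain")
  writeReleaseFiles(tabs, dir)
  idx <- parseRelease(releasePaths(dir))
  expect_identical(resolvePrimary(idx, 5L), 1L)
  expect_identical(resolvePrimary(idx, 3L), 1L)
  expect_identical(resolvePrimary(idx, 1L), 1L)   # idempotent
  expect_setequal(groupMembers(idx, 1L), c(1L, 3L, 5L))
  expect_identical(groupMembers(idx, 5L)[1L], 1L) # primary first
  expect_error(resolvePrimary(idx, 99L), class = "chebi_undefined_id")
})

test_that("dangling parents and parent cycles are rejected by name", {
  base <- data.frame(
    ID = c(1L, 2L), STATUS = "C",
    CHEBI_ACCESSION = c("CHEBI:1", "CHEBI:2"), SOURCE = "ChEBI",
    PARENT_ID = c(NA_integer_, 7L), NAME = "x",
    DEFINITION = NA_character_, MODIFIED_ON = "2020-01-01",
    CREATED_BY = NA_character_, STAR = 3L, stringsAsFactors = FALSE)
  d1 <- tempfile(); writeReleaseFiles(list(compounds = base), d1)
  expect_error(parseRelease(releasePaths(d1)),
               class = "chebi_dangling_parent")

  cyc <- base
  cyc$PARENT_ID <- c(2L, 1L)
  d2 <- tempfile(); writeReleaseFiles(list(compounds = cyc), d2)
  expect_error(parseRelease(releasePaths(d2)),
               class = "chebi_cyclic_parents")
})

test_that("malformed rows are skipped with a warning, or abort in
           strict mode", {
  fx <- generateFixture(fixtureSpec(nPrimary = 4L, nSecondary = 0L,
                                    seed = 2L))
  path <- file.path(fx$dir, "names.tsv")
  writeLines(c(readLines(path), "too\tfew\tcolumns"), path)
  expect_warning(idx <- parseRelease(releasePaths(fx$dir)),
                 "malformed")
  expect_identical(unname(idx@skipped[["names"]]), 1L)
  expect_error(parseRelease(releasePaths(fx$dir), strict = TRUE),
               class = "chebi_malformed_row")
})

test_that("CRLF line endings parse identically to LF", {
  fx <- generateFixture(fixtureSpec(nPrimary = 6L, nSecondary = 3L,
                                    seed = 9L))
  ## the generator writes comments.tsv with CRLF endings by design
  rawBytes <- readBin(file.path(fx$dir, "comments.tsv"), raw(), 1e6)
  expect_true(any(rawBytes == as.raw(0x0d)))
  idx <- parseRelease(releasePaths(fx$dir), strict = TRUE)
  expect_identical(idx@comments, fx$manifest$tables$comments)
})

test_that("every relation appears exactly once in outgoing and once in
           incoming (duality)", {
  fx <- generateFixture(fixtureSpec(nPrimary = 12L, nSecondary = 4L,
                                    relationDensity = 2.5, seed = 31L))
  idx <- parseRelease(releasePaths(fx$dir))
  rel <- idx@relations
  expect_gt(nrow(rel), 0L)
  outIdx <- sort(unlist(idx@outgoing, use.names = FALSE))
  inIdx <- sort(unlist(idx@incoming, use.names = FALSE))
  expect_identical(outIdx, seq_len(nrow(rel)))
  expect_identical(inIdx, seq_len(nrow(rel)))
  for (i in seq_len(nrow(rel))) {
    expect_true(i %in% idx@outgoing[[as.character(rel$INIT_ID[i])]])
    expect_true(i %in% idx@incoming[[as.character(rel$FINAL_ID[i])]])
  }
})

test_that("the relation direction switch inverts the convention", {
  fx <- generateFixture(fixtureSpec(nPrimary = 6L, nSecondary = 0L,
                                    relationDensity = 2, seed = 13L))
  a <- parseRelease(releasePaths(fx$dir))
  b <- parseRelease(releasePaths(fx$dir),
                    relationDirection = "final_outgoing")
  expect_identical(a@relations$INIT_ID, b@relations$FINAL_ID)
  expect_identical(a@relations$FINAL_ID, b@relations$INIT_ID)
})

test_that("structure and reference records are not reachable from the
           index (memory contract)", {
  fx <- generateFixture(fixtureSpec(nPrimary = 6L, nSecondary = 2L,
                                    seed = 11L))
  idx <- parseRelease(releasePaths(fx$dir))
  for (s in slotNames(idx)) {
    v <- slot(idx, s)
    if (is.data.frame(v))
      expect_false("STRUCTURE" %in% names(v) ||
                     "REFERENCE_ID" %in% names(v), info = s)
  }
  ## only paths are held
  expect_type(idx@structuresPath, "character")
  expect_type(idx@referencesPath, "character")
})

test_that("streamStructure returns the default molfile byte-identical
           to the manifest, preferring defaults and keeping quoting",
{
  fx <- generateFixture(fixtureSpec(nPrimary = 8L, nSecondary = 2L,
                                    seed = 5L))
  strs <- fx$manifest$tables$structures
  mols <- strs[strs$TYPE == "mol", ]
  twoMol <- names(which(table(mols$COMPOUND_ID) == 2L))[1L]
  expect_false(is.na(twoMol))  # generator guarantees one such compound
  path <- file.path(fx$dir, "structures.csv")

  rec <- streamStructure(as.integer(twoMol), "mol", path)
  wanted <- mols[mols$COMPOUND_ID == as.integer(twoMol) &
                   mols$DEFAULT_STRUCTURE == "Y", ]
  expect_identical(rec$STRUCTURE, wanted$STRUCTURE[[1L]])
  expect_true(grepl("\n", rec$STRUCTURE))        # multi-line survived
  expect_true(grepl("\"", rec$STRUCTURE))        # embedded quotes too

  ## absent compound or type -> NULL
  expect_null(streamStructure(999999L, "mol", path))
})

test_that("streamReferences returns all and only the compound's rows
           in file order, independently of call order", {
  fx <- generateFixture(fixtureSpec(nPrimary = 6L, nSecondary = 2L,
                                    seed = 3L))
  refs <- fx$manifest$tables$reference
  path <- file.path(fx$dir, "reference.tsv")
  three <- as.integer(names(which(table(refs$COMPOUND_ID) == 3L))[1L])
  got <- streamReferences(three, path)
  want <- refs[refs$COMPOUND_ID == three, ]
  rownames(want) <- NULL
  expect_identical(got, want)
  expect_identical(nrow(got), 3L)

  ## permutation: interleaving other lookups does not change results
  other <- unique(refs$COMPOUND_ID)[1L]
  streamReferences(other, path)
  expect_identical(streamReferences(three, path), want)
  expect_identical(nrow(streamReferences(999999L, path)), 0L)
})
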