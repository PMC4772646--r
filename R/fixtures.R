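## Deterministic generator of miniature, internally consistent
## ChEBI-style releases, plus the ground-truth manifest used as the
## oracle by the test suite.  The generator is a public part of the
## package: downstream users need offline fixtures too.

.nameVocab <- c(
  "water", "D-glucose", "aldohexose", "ethanol", "glycine", "adenosine",
  "caffeine", "benzene", "pyruvate", "citrate", "urea", "L-lactate",
  "sucrose", "L-serine", "L-histidine", "cholesterol", "glycerol",
  "acetate", "fumarate", "malate")

.formulaVocab <- c(
  "H2O", "C6H12O6", "C2H6O", "C2H5NO2", "C10H13N5O4", "C8H10N4O2",
  "C6H6", "C3H4O3", "C6H8O7", "CH4N2O", "C3H6O3", "C12H22O11",
  "C3H7NO3", "C6H9N3O2", "C27H46O", "C3H8O3", "C2H4O2", "C4H4O4",
  "C4H6O5")

.relationTypes <- c(
  "is_a", "has_part", "has_role", "is_conjugate_acid_of",
  "is_conjugate_base_of", "is_tautomer_of", "is_enantiomer_of",
  "has_functional_parent", "has_parent_hydride",
  "is_substituent_group_from")

.speciesVocab <- data.frame(
  SPECIES_TEXT = c("Homo sapiens", "Escherichia coli",
                   "Saccharomyces cerevisiae", "Arabidopsis thaliana"),
  SPECIES_ACCESSION = c("NCBI:txid9606", "NCBI:txid562", "NCBI:txid4932",
                        "NCBI:txid3702"),
  stringsAsFactors = FALSE)

## A small V2000 molfile with the compound name as title.  `quoted`
## adds embedded double quotes to exercise the CSV dialect.
.molfileFor <- function(title, quoted = FALSE) {
  if (quoted) title <- paste0(title, " (\"mini\" fixture)")
  paste(c(
    title,
    "  chebir fixture",
    "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.8660    0.5000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.8660    0.5000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0",
    "  1  3  1  0",
    "M  END"), collapse = "\n")
}

#' Construct a fixture specification
#'
#' @param nPrimary Number of primary compounds.
#' @param nSecondary Number of secondary (merged) compounds.
#' @param maxParentChain Maximum parent-chain depth; at least 2 lets
#'   the generator build secondary-of-secondary chains.
#' @param relationDensity Expected ontology relations per primary.
#' @param seed Integer seed; identical spec and seed give
#'   byte-identical output.
#' @param include Optional tables to emit (default: all of them).
#' @return A [FixtureSpec-class].
#' @examples
#' fixtureSpec(nPrimary = 5, nSecondary = 2, seed = 7)
#' @export
fixtureSpec <- function(nPrimary = 10L, nSecondary = 5L,
                        maxParentChain = 2L, relationDensity = 1.5,
                        seed = 1L,
                        include = setdiff(chebiFileNames(), "compounds")) {
  new("FixtureSpec", nPrimary = as.integer(nPrimary),
      nSecondary = as.integer(nSecondary),
      maxParentChain = as.integer(maxParentChain),
      relationDensity = as.numeric(relationDensity),
      seed = as.integer(seed), include = include)
}

#' @describeIn FixtureSpec-class Compact summary of the spec.
#' @param object A `FixtureSpec`.
#' @export
setMethod("show", "FixtureSpec", function(object) {
  cat(sprintf(
    "FixtureSpec: %d primary + %d secondary, chain <= %d, density %.2f, seed %d\n",
    object@nPrimary, object@nSecondary, object@maxParentChain,
    object@relationDensity, object@seed))
  invisible(object)
})

## ---- model construction ----

.emptyTables <- function(include) {
  tabs <- lapply(chebiFileNames(), .emptyTable)
  names(tabs) <- chebiFileNames()
  tabs[c("compounds", intersect(chebiFileNames(), include))]
}

## Build the full set of typed tables for a spec.  Runs under its own
## RNG state so callers' random streams are untouched.
.buildFixtureTables <- function(spec) {
  if (spec@nSecondary > 0L && spec@nPrimary == 0L)
    stopChebi("unsatisfiable fixture spec: secondaries require at least one primary",
              "chebi_unsatisfiable_spec")
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(oldSeed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", oldSeed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec@seed)

  tabs <- .emptyTables(spec@include)
  n <- spec@nPrimary + spec@nSecondary
  if (n == 0L) return(tabs)

  ## ids with gaps, so unknown-id lookups have room below max(id)
  ids <- sort(sample.int(max(2L * n, 4L), n))
  roles <- rep("primary", n)
  if (spec@nSecondary > 0L)
    roles[sample.int(n, spec@nSecondary)] <- "secondary"
  primaries <- ids[roles == "primary"]
  secondaries <- ids[roles == "secondary"]

  ## parent assignment: chains never exceed maxParentChain; force one
  ## chain of depth >= 2 when the spec allows it
  depth <- structure(rep(0L, length(primaries)),
                     names = as.character(primaries))
  parent <- structure(integer(0), names = character(0))
  for (k in seq_along(secondaries)) {
    s <- secondaries[[k]]
    pool <- as.integer(names(depth))[depth < spec@maxParentChain &
                                       as.integer(names(depth)) != s]
    if (k == 2L && spec@maxParentChain >= 2L &&
        depth[[as.character(secondaries[[1L]])]] < spec@maxParentChain) {
      p <- secondaries[[1L]]
    } else {
      p <- if (length(pool) == 1L) pool else sample(pool, 1L)
    }
    parent[[as.character(s)]] <- p
    depth[[as.character(s)]] <- depth[[as.character(p)]] + 1L
  }

  nameFor <- function(i) {
    base <- .nameVocab[((i - 1L) %% length(.nameVocab)) + 1L]
    if (i > length(.nameVocab)) paste0(base, " ", i) else base
  }
  compoundNames <- vapply(seq_len(n), nameFor, "")
  names(compoundNames) <- as.character(ids)

  isSec <- ids %in% secondaries
  tabs$compounds <- data.frame(
    ID = ids,
    STATUS = ifelse(isSec, sample(c("O", "D", "C"), n, replace = TRUE),
                    sample(c("C", "S", "E"), n, replace = TRUE)),
    CHEBI_ACCESSION = chebiAccession(ids),
    SOURCE = sample(c("ChEBI", "KEGG COMPOUND", "SUBMITTER"), n,
                    replace = TRUE),
    PARENT_ID = ifelse(isSec, unname(parent[as.character(ids)]),
                       NA_integer_),
    NAME = ifelse(isSec & stats::runif(n) < 0.5, NA_character_,
                  unname(compoundNames)),
    DEFINITION = ifelse(stats::runif(n) < 0.6,
                        paste("A fixture entity modelled on",
                              unname(compoundNames)),
                        NA_character_),
    MODIFIED_ON = sprintf("20%02d-%02d-%02d",
                          sample(10:25, n, replace = TRUE),
                          sample(1:12, n, replace = TRUE),
                          sample(1:28, n, replace = TRUE)),
    CREATED_BY = ifelse(stats::runif(n) < 0.7,
                        sample(c("curator_a", "curator_b", "submitter"),
                               n, replace = TRUE),
                        NA_character_),
    STAR = sample(2:3, n, replace = TRUE),
    stringsAsFactors = FALSE)

  rowId <- local({i <- 0L; function() {i <<- i + 1L; i}})

  if ("names" %in% names(tabs)) {
    rows <- list()
    for (i in seq_len(n)) {
      cnt <- sample(0:3, 1L)
      for (j in seq_len(cnt))
        rows[[length(rows) + 1L]] <- data.frame(
          ID = rowId(), COMPOUND_ID = ids[[i]],
          TYPE = sample(c("SYNONYM", "IUPAC NAME", "INN", "BRAND NAME"),
                        1L),
          SOURCE = sample(c("ChEBI", "KEGG COMPOUND", "IUPAC"), 1L),
          NAME = paste0(compoundNames[[i]], " syn", j),
          ADAPTED = sample(c("T", "F"), 1L),
          LANGUAGE = sample(c("en", "de", "la"), 1L),
          stringsAsFactors = FALSE)
    }
    ## a duplicate synonym shared by a primary and its secondary, to
    ## exercise cross-group deduplication
    if (length(secondaries)) {
      s <- secondaries[[1L]]
      p <- parent[[as.character(s)]]
      dup <- function(cid) data.frame(
        ID = rowId(), COMPOUND_ID = cid, TYPE = "SYNONYM",
        SOURCE = "ChEBI", NAME = "shared synonym", ADAPTED = "F",
        LANGUAGE = "en", stringsAsFactors = FALSE)
      rows <- c(rows, list(dup(p), dup(s)))
    }
    if (length(rows)) tabs$names <- do.call(rbind, rows)
  }

  if ("chemical_data" %in% names(tabs)) {
    rows <- list()
    for (i in seq_len(n)) {
      cid <- ids[[i]]
      sec <- isSec[[i]]
      formula <- .formulaVocab[((i - 1L) %% length(.formulaVocab)) + 1L]
      addRow <- function(type, value) rows[[length(rows) + 1L]] <<-
        data.frame(ID = rowId(), COMPOUND_ID = cid,
                   SOURCE = sample(c("ChEBI", "KEGG COMPOUND"), 1L),
                   TYPE = type, CHEMICAL_DATA = value,
                   stringsAsFactors = FALSE)
      pData <- if (sec) 0.3 else 0.9      # secondaries rarely keep data
      if (stats::runif(1) < pData) addRow("FORMULA", formula)
      if (stats::runif(1) < pData)
        addRow("MASS", sprintf("%.5f", stats::runif(1, 10, 900)))
      if (stats::runif(1) < pData)
        addRow("CHARGE", sprintf("%d", sample(-4:4, 1L)))
      if (stats::runif(1) < pData * 0.7)
        addRow("MONOISOTOPIC MASS",
               sprintf("%.5f", stats::runif(1, 10, 900)))
    }
    if (length(rows)) tabs$chemical_data <- do.call(rbind, rows)
  }

  if ("database_accession" %in% names(tabs)) {
    rows <- list()
    for (i in seq_len(n)) {
      cnt <- sample(0:2, 1L)
      for (j in seq_len(cnt))
        rows[[length(rows) + 1L]] <- data.frame(
          ID = rowId(), COMPOUND_ID = ids[[i]],
          SOURCE = sample(c("ChEBI", "KEGG COMPOUND", "SUBMITTER"), 1L),
          TYPE = sample(c("KEGG COMPOUND accession",
                          "CAS Registry Number", "HMDB accession"), 1L),
          ACCESSION_NUMBER = sprintf("X%05d", sample.int(99999L, 1L)),
          stringsAsFactors = FALSE)
    }
    if (length(rows)) tabs$database_accession <- do.call(rbind, rows)
  }

  if ("relation" %in% names(tabs) && length(primaries) >= 2L) {
    nRel <- min(round(spec@relationDensity * length(primaries)),
                length(primaries) * (length(primaries) - 1L))
    if (nRel > 0L) {
      pairs <- expand.grid(INIT_ID = primaries, FINAL_ID = primaries)
      pairs <- pairs[pairs$INIT_ID != pairs$FINAL_ID, , drop = FALSE]
      pick <- sample.int(nrow(pairs), nRel)
      tabs$relation <- data.frame(
        ID = vapply(seq_len(nRel), function(i) rowId(), 0L),
        TYPE = sample(.relationTypes, nRel, replace = TRUE),
        INIT_ID = pairs$INIT_ID[pick],
        FINAL_ID = pairs$FINAL_ID[pick],
        STATUS = sample(c("C", "E"), nRel, replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }

  if ("inchi" %in% names(tabs)) {
    keep <- ids[stats::runif(n) < ifelse(isSec, 0.3, 0.8)]
    if (length(keep))
      tabs$inchi <- data.frame(
        CHEBI_ID = keep,
        INCHI = paste0("InChI=1S/",
                       vapply(match(keep, ids), function(i)
                         .formulaVocab[((i - 1L) %% length(.formulaVocab)) + 1L],
                         ""),
                       "/fixture", keep),
        stringsAsFactors = FALSE)
  }

  if ("comments" %in% names(tabs)) {
    rows <- list()
    for (i in seq_len(n)) {
      cnt <- sample(0:2, 1L)
      for (j in seq_len(cnt))
        rows[[length(rows) + 1L]] <- data.frame(
          ID = rowId(), COMPOUND_ID = ids[[i]],
          CREATED_ON = sprintf("20%02d-%02d-%02d",
                               sample(10:25, 1L), sample(1:12, 1L),
                               sample(1:28, 1L)),
          DATATYPE = sample(c("General", "DatabaseAccession"), 1L),
          TEXT = paste("fixture comment", j, "on",
                       compoundNames[[i]]),
          stringsAsFactors = FALSE)
    }
    if (length(rows)) tabs$comments <- do.call(rbind, rows)
  }

  if ("reference" %in% names(tabs)) {
    rows <- list()
    for (i in seq_len(n)) {
      ## the first compound always carries three rows, exercising the
      ## multi-row streaming path
      cnt <- if (i == 1L) 3L else sample(0:2, 1L)
      for (j in seq_len(cnt))
        rows[[length(rows) + 1L]] <- data.frame(
          COMPOUND_ID = ids[[i]],
          REFERENCE_ID = sprintf("%d", sample.int(999999L, 1L)),
          REFERENCE_DB_NAME = sample(c("PubMed", "Reaxys", "Wikipedia"),
                                     1L),
          LOCATION_IN_REF = if (stats::runif(1) < 0.5) NA_character_
                            else sprintf("p%d", sample.int(40L, 1L)),
          REFERENCE_NAME = paste("reference", j, "for",
                                 compoundNames[[i]]),
          stringsAsFactors = FALSE)
    }
    if (length(rows)) tabs$reference <- do.call(rbind, rows)
  }

  if ("compound_origins" %in% names(tabs)) {
    rows <- list()
    for (i in seq_len(n)) {
      if (stats::runif(1) < 0.4) {
        sp <- .speciesVocab[sample.int(nrow(.speciesVocab), 1L), ]
        rows[[length(rows) + 1L]] <- data.frame(
          ID = rowId(), COMPOUND_ID = ids[[i]],
          SPECIES_TEXT = sp$SPECIES_TEXT,
          SPECIES_ACCESSION = sp$SPECIES_ACCESSION,
          COMPONENT_TEXT = if (stats::runif(1) < 0.5) "cytoplasm"
                           else NA_character_,
          STRAIN_TEXT = NA_character_,
          SOURCE_TYPE = "MetaboLights",
          SOURCE_ACCESSION = sprintf("MTBLS%d", sample.int(999L, 1L)),
          COMMENTS = NA_character_, stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) tabs$compound_origins <- do.call(rbind, rows)
  }

  if ("structures" %in% names(tabs)) {
    rows <- list()
    firstMol <- TRUE
    for (i in seq_len(n)) {
      if (isSec[[i]] && stats::runif(1) < 0.7) next
      cid <- ids[[i]]
      if (stats::runif(1) < 0.7) {
        ## default 2D mol; the first one embeds quotes in its title
        rows[[length(rows) + 1L]] <- data.frame(
          ID = rowId(), COMPOUND_ID = cid,
          STRUCTURE = .molfileFor(compoundNames[[i]], quoted = firstMol),
          TYPE = "mol", DIMENSION = "2D", DEFAULT_STRUCTURE = "Y",
          stringsAsFactors = FALSE)
        if (firstMol) {
          ## and a second, non-default mol for the prefer-default path
          rows[[length(rows) + 1L]] <- data.frame(
            ID = rowId(), COMPOUND_ID = cid,
            STRUCTURE = .molfileFor(paste(compoundNames[[i]], "3D")),
            TYPE = "mol", DIMENSION = "2D", DEFAULT_STRUCTURE = "N",
            stringsAsFactors = FALSE)
        }
        firstMol <- FALSE
      }
      if (stats::runif(1) < 0.6)
        rows[[length(rows) + 1L]] <- data.frame(
          ID = rowId(), COMPOUND_ID = cid,
          STRUCTURE = paste0("C", paste(rep("C", i %% 5L), collapse = "")),
          TYPE = "SMILES", DIMENSION = "1D", DEFAULT_STRUCTURE = "Y",
          stringsAsFactors = FALSE)
      if (stats::runif(1) < 0.6)
        rows[[length(rows) + 1L]] <- data.frame(
          ID = rowId(), COMPOUND_ID = cid,
          STRUCTURE = sprintf("FIXTUREKEY%014d-UHFFFAOYSA-N", cid),
          TYPE = "InChIKey", DIMENSION = "1D", DEFAULT_STRUCTURE = "Y",
          stringsAsFactors = FALSE)
    }
    if (length(rows)) tabs$structures <- do.call(rbind, rows)
  }

  for (nm in names(tabs)) rownames(tabs[[nm]]) <- NULL
  tabs
}

## ---- serialisation ----

.formatField <- function(v) {
  out <- as.character(v)
  out[is.na(v)] <- .NULL_TOKEN
  out
}

.csvField <- function(v, forceQuote = FALSE) {
  out <- .formatField(v)
  need <- forceQuote | grepl('[",\n\r]', out)
  out[need] <- paste0('"', gsub('"', '""', out[need]), '"')
  out
}

.writeBytes <- function(text, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(text)), con)
  invisible(path)
}

#' Write release flat files from a set of tables
#'
#' Renders typed tables in the release dialects: tab-separated with a
#' header row and `"null"` for absent values (the comments table uses
#' CRLF line endings, exercising both conventions), and RFC-4180
#' quoted CSV for structures, whose STRUCTURE field is always quoted
#' so molfile text survives verbatim.  Also emits a gzipped variant of
#' each file.  Purely deterministic: the same tables always produce
#' byte-identical files.
#'
#' @param tables Named list of typed data.frames as produced by the
#'   fixture generator (or by [parseRelease()] consumers).
#' @param dir Output directory, created if needed.
#' @param gzip Also write `<file>.gz` beside each flat file.
#' @return Invisibly, the named vector of file paths written.
#' @export
writeReleaseFiles <- function(tables, dir, gzip = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in intersect(chebiFileNames(), names(tables))) {
    schema <- .chebiSchemas[[nm]]
    tab <- tables[[nm]]
    path <- file.path(dir, schema$file)
    if (schema$dialect == "tsv") {
      eol <- if (nm == "comments") "\r\n" else "\n"
      header <- paste(names(schema$cols), collapse = "\t")
      body <- if (nrow(tab)) {
        cells <- lapply(names(schema$cols), function(cn)
          .formatField(tab[[cn]]))
        do.call(paste, c(cells, sep = "\t"))
      } else character(0)
      .writeBytes(paste0(paste(c(header, body), collapse = eol), eol),
                  path)
    } else {
      header <- paste(names(schema$cols), collapse = ",")
      body <- if (nrow(tab)) {
        cells <- lapply(names(schema$cols), function(cn)
          .csvField(tab[[cn]], forceQuote = cn == "STRUCTURE"))
        do.call(paste, c(cells, sep = ","))
      } else character(0)
      .writeBytes(paste0(paste(c(header, body), collapse = "\n"), "\n"),
                  path)
    }
    paths[[nm]] <- path
    if (gzip) {
      gz <- gzcon(file(paste0(path, ".gz"), open = "wb"))
      writeBin(readBin(path, raw(), file.size(path)), gz)
      close(gz)
    }
  }
  invisible(paths)
}

## ---- ground-truth manifest ----

## Brute-force expected getter outputs, computed directly from the
## generator's tables (never through the parser or entity code); this
## is the oracle the test suite compares the implementation against.
.expectedEntities <- function(tables) {
  cmp <- tables$compounds
  if (!nrow(cmp)) return(list())
  parent <- structure(cmp$PARENT_ID, names = as.character(cmp$ID))
  resolve <- function(id) {
    cur <- id
    repeat {
      p <- parent[[as.character(cur)]]
      if (is.na(p)) return(cur)
      cur <- p
    }
  }
  primaryOf <- vapply(cmp$ID, resolve, 0L)
  names(primaryOf) <- as.character(cmp$ID)

  tab <- function(nm) if (!is.null(tables[[nm]])) tables[[nm]]
                      else .emptyTable(nm)
  nms <- tab("names"); chem <- tab("chemical_data")
  acc <- tab("database_accession"); rel <- tab("relation")
  inchi <- tab("inchi"); cmts <- tab("comments")
  refs <- tab("reference"); orig <- tab("compound_origins")
  strs <- tab("structures")

  dedupBy <- function(df, cols = names(df)) {
    if (!nrow(df)) return(df)
    key <- do.call(paste, c(lapply(cols, function(cn)
      ifelse(is.na(df[[cn]]), "\x01NA", df[[cn]])), sep = "\x02"))
    out <- df[!duplicated(key), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  memberRows <- function(df, members, idCol = "COMPOUND_ID") {
    out <- do.call(rbind, lapply(members, function(m)
      df[df[[idCol]] == m, , drop = FALSE]))
    if (is.null(out)) out <- df[0L, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  firstChem <- function(members, type) {
    rows <- memberRows(chem, members)
    rows <- rows[rows$TYPE == type, , drop = FALSE]
    if (nrow(rows)) rows$CHEMICAL_DATA[[1L]] else NA_character_
  }
  pickStructure <- function(members, type, dimension = NULL) {
    for (m in members) {
      rows <- strs[strs$COMPOUND_ID == m & strs$TYPE == type, ,
                   drop = FALSE]
      if (!is.null(dimension))
        rows <- rows[rows$DIMENSION == dimension, , drop = FALSE]
      if (nrow(rows)) {
        def <- rows$DEFAULT_STRUCTURE == "Y"
        return(rows$STRUCTURE[[if (any(def)) which(def)[1L] else 1L]])
      }
    }
    NA_character_
  }
  relationsOf <- function(members, direction) {
    ownCol <- if (direction == "out") "INIT_ID" else "FINAL_ID"
    otherCol <- if (direction == "out") "FINAL_ID" else "INIT_ID"
    rows <- rel[rel[[ownCol]] %in% members, , drop = FALSE]
    out <- data.frame(TYPE = rows$TYPE,
                      TARGET = chebiAccession(rows[[otherCol]]),
                      STATUS = rows$STATUS, stringsAsFactors = FALSE)
    out <- out[order(out$TYPE, rows[[otherCol]]), , drop = FALSE]
    rownames(out) <- NULL
    dedupBy(out)
  }

  entities <- lapply(seq_len(nrow(cmp)), function(i) {
    id <- cmp$ID[[i]]
    p <- primaryOf[[as.character(id)]]
    members <- c(p, sort(setdiff(cmp$ID[primaryOf == p], p)))
    prow <- cmp[cmp$ID == p, , drop = FALSE]
    nameRows <- memberRows(nms, members)
    chg <- firstChem(members, "CHARGE")
    mass <- firstChem(members, "MASS")
    mono <- firstChem(members, "MONOISOTOPIC MASS")
    inchiText <- NA_character_
    for (m in members) {
      hit <- inchi$INCHI[inchi$CHEBI_ID == m]
      if (length(hit)) {inchiText <- hit[[1L]]; break}
    }
    formRows <- memberRows(chem, members)
    formRows <- formRows[formRows$TYPE == "FORMULA", , drop = FALSE]
    list(
      id = chebiAccession(id),
      parent_id = chebiAccession(parent[[as.character(id)]]),
      primary_id = p,
      name = prow$NAME, definition = prow$DEFINITION,
      status = prow$STATUS, source = prow$SOURCE,
      created_by = prow$CREATED_BY, modified_on = prow$MODIFIED_ON,
      star = prow$STAR,
      names = dedupBy(nameRows[, c("NAME", "TYPE", "SOURCE", "ADAPTED",
                                   "LANGUAGE"), drop = FALSE],
                      c("NAME", "TYPE", "LANGUAGE")),
      formula = firstChem(members, "FORMULA"),
      formulae = dedupBy(data.frame(FORMULA = formRows$CHEMICAL_DATA,
                                    SOURCE = formRows$SOURCE,
                                    stringsAsFactors = FALSE)),
      mass = if (is.na(mass)) NA_real_ else as.numeric(mass),
      charge = if (is.na(chg)) NA_integer_ else as.integer(chg),
      monoisotopic_mass = if (is.na(mono)) NA_real_
                          else as.numeric(mono),
      accessions = dedupBy(memberRows(acc, members)[,
        c("SOURCE", "TYPE", "ACCESSION_NUMBER"), drop = FALSE]),
      comments = dedupBy(memberRows(cmts, members)[,
        c("CREATED_ON", "DATATYPE", "TEXT"), drop = FALSE]),
      origins = dedupBy(memberRows(orig, members)[,
        setdiff(names(orig), c("ID", "COMPOUND_ID")), drop = FALSE]),
      inchi = inchiText,
      inchikey = pickStructure(members, "InChIKey"),
      smiles = pickStructure(members, "SMILES"),
      mol = pickStructure(members, "mol", "2D"),
      outgoings = relationsOf(members, "out"),
      incomings = relationsOf(members, "in"),
      references = dedupBy(memberRows(refs, members)))
  })
  names(entities) <- as.character(cmp$ID)
  entities
}

.buildManifest <- function(tables, specInfo) {
  cmp <- tables$compounds
  parentOf <- if (nrow(cmp)) {
    sel <- !is.na(cmp$PARENT_ID)
    structure(cmp$PARENT_ID[sel], names = as.character(cmp$ID[sel]))
  } else structure(integer(0), names = character(0))
  entities <- .expectedEntities(tables)
  primaryOf <- vapply(entities, function(e) e$primary_id, 0L)
  groupOf <- if (length(primaryOf))
    lapply(split(as.integer(names(primaryOf)), primaryOf), sort)
  else list()
  list(spec = specInfo, tables = tables, parentOf = parentOf,
       primaryOf = primaryOf, groupOf = groupOf, entities = entities)
}

#' Generate a miniature release with its ground-truth manifest
#'
#' Emits every requested flat file (plus gzipped variants) under `dir`,
#' together with `manifest.json`, and returns the in-memory manifest:
#' the complete ground truth of the generated release, including the
#' expected output of every entity getter for every compound, computed
#' directly from the generator's model.  Identical spec and seed
#' always give byte-identical output; parent links form chains up to
#' the requested depth; relations connect primary compounds only; at
#' least one compound carries a multi-line molfile with embedded
#' quotes; `"null"` sentinels are sprinkled deterministically.
#'
#' @param spec A [fixtureSpec()].
#' @param dir Output directory (default: a fresh directory under the
#'   session temp dir).
#' @return Invisibly, `list(dir = <release directory>,
#'   manifest = <ground truth>)`.
#' @section Errors: `chebi_unsatisfiable_spec` when the spec cannot be
#'   realised (secondaries without any primary).
#' @examples
#' fx <- generateFixture(fixtureSpec(nPrimary = 4, nSecondary = 2,
#'                                   seed = 11))
#' names(fx$manifest$entities)
#' @export
generateFixture <- function(spec = fixtureSpec(),
                            dir = tempfile("chebir-fixture")) {
  stopifnot(is(spec, "FixtureSpec"))
  validObject(spec)
  tables <- .buildFixtureTables(spec)
  writeReleaseFiles(tables, dir)
  manifest <- .buildManifest(tables, list(
    nPrimary = spec@nPrimary, nSecondary = spec@nSecondary,
    maxParentChain = spec@maxParentChain,
    relationDensity = spec@relationDensity, seed = spec@seed))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "columns", auto_unbox = TRUE,
                       na = "null", digits = NA)
  invisible(list(dir = dir, manifest = manifest))
}

#' The canonical hand-written mini-release
#'
#' A fixed four-compound release used throughout the documentation:
#' CHEBI:1 "water" (formula H2O, charge 0, mass 18.0153, InChI,
#' default 2D molfile), CHEBI:2 a secondary merged into water carrying
#' the synonym "WATER", CHEBI:3 "D-glucose" (formula C6H12O6, charge 0,
#' several synonyms, SMILES and InChIKey) and CHEBI:4 "aldohexose",
#' with the ontology relation D-glucose `is_a` aldohexose.
#'
#' The release is written once per session under the temp directory
#' and reused.
#'
#' @return `list(dir = <release directory>, manifest = <ground truth>)`.
#' @examples
#' rel <- canonicalMiniRelease()
#' getName(ChebiEntity("CHEBI:3", rel$dir))
#' @export
canonicalMiniRelease <- function() {
  dir <- file.path(tempdir(), "chebir-canonical")
  tables <- .canonicalTables()
  if (!file.exists(file.path(dir, "compounds.tsv")))
    writeReleaseFiles(tables, dir)
  manifest <- .buildManifest(tables, list(canonical = TRUE))
  list(dir = dir, manifest = manifest)
}

.canonicalTables <- function() {
  tabs <- .emptyTables(setdiff(chebiFileNames(), "compounds"))
  tabs$compounds <- data.frame(
    ID = 1:4, STATUS = c("C", "O", "C", "C"),
    CHEBI_ACCESSION = chebiAccession(1:4),
    SOURCE = "ChEBI",
    PARENT_ID = c(NA_integer_, 1L, NA_integer_, NA_integer_),
    NAME = c("water", NA, "D-glucose", "aldohexose"),
    DEFINITION = c("An oxygen hydride consisting of an oxygen atom bonded to two hydrogen atoms.",
                   NA,
                   "The D-enantiomer of glucose, an aldohexose found widely in nature.",
                   "A hexose with a (potential) aldehyde group at C-1."),
    MODIFIED_ON = c("2016-01-15", "2010-06-01", "2016-01-15",
                    "2014-03-20"),
    CREATED_BY = c("curator_a", "curator_a", "curator_b", "curator_b"),
    STAR = c(3L, 3L, 3L, 3L), stringsAsFactors = FALSE)
  tabs$names <- data.frame(
    ID = 1:6, COMPOUND_ID = c(1L, 2L, 3L, 3L, 3L, 4L),
    TYPE = c("SYNONYM", "SYNONYM", "SYNONYM", "SYNONYM", "IUPAC NAME",
             "SYNONYM"),
    SOURCE = c("ChEBI", "KEGG COMPOUND", "ChEBI", "KEGG COMPOUND",
               "IUPAC", "ChEBI"),
    NAME = c("H2O", "WATER", "dextrose", "grape sugar", "D-glucopyranose",
             "aldohexoses"),
    ADAPTED = "F", LANGUAGE = "en", stringsAsFactors = FALSE)
  tabs$chemical_data <- data.frame(
    ID = 1:7, COMPOUND_ID = c(1L, 1L, 1L, 3L, 3L, 3L, 4L),
    SOURCE = "ChEBI",
    TYPE = c("FORMULA", "MASS", "CHARGE", "FORMULA", "MASS", "CHARGE",
             "FORMULA"),
    CHEMICAL_DATA = c("H2O", "18.0153", "0", "C6H12O6", "180.15588",
                      "0", "C6H12O6"),
    stringsAsFactors = FALSE)
  tabs$database_accession <- data.frame(
    ID = 1:2, COMPOUND_ID = c(1L, 3L), SOURCE = "KEGG COMPOUND",
    TYPE = "KEGG COMPOUND accession",
    ACCESSION_NUMBER = c("C00001", "C00031"), stringsAsFactors = FALSE)
  tabs$relation <- data.frame(
    ID = 1L, TYPE = "is_a", INIT_ID = 3L, FINAL_ID = 4L, STATUS = "C",
    stringsAsFactors = FALSE)
  tabs$inchi <- data.frame(
    CHEBI_ID = c(1L, 3L),
    INCHI = c("InChI=1S/H2O/h1H2",
              "InChI=1S/C6H12O6/c7-1-2-3(8)4(9)5(10)6(11)12-2/h2-11H,1H2/t2-,3-,4+,5-,6?/m1/s1"),
    stringsAsFactors = FALSE)
  tabs$comments <- data.frame(
    ID = 1L, COMPOUND_ID = 3L, CREATED_ON = "2015-11-02",
    DATATYPE = "General",
    TEXT = "Widely used carbon source in cell culture.",
    stringsAsFactors = FALSE)
  tabs$reference <- data.frame(
    COMPOUND_ID = c(1L, 3L, 3L),
    REFERENCE_ID = c("10592235", "10592235", "23456789"),
    REFERENCE_DB_NAME = c("PubMed", "PubMed", "PubMed"),
    LOCATION_IN_REF = c(NA, NA, "fig 2"),
    REFERENCE_NAME = c("Nucleic Acids Res fixture reference",
                       "Nucleic Acids Res fixture reference",
                       "J Cheminform fixture reference"),
    stringsAsFactors = FALSE)
  tabs$compound_origins <- data.frame(
    ID = 1L, COMPOUND_ID = 3L, SPECIES_TEXT = "Homo sapiens",
    SPECIES_ACCESSION = "NCBI:txid9606", COMPONENT_TEXT = "blood",
    STRAIN_TEXT = NA_character_, SOURCE_TYPE = "MetaboLights",
    SOURCE_ACCESSION = "MTBLS90", COMMENTS = NA_character_,
    stringsAsFactors = FALSE)
  tabs$structures <- data.frame(
    ID = 1:4, COMPOUND_ID = c(1L, 1L, 3L, 3L),
    STRUCTURE = c(.molfileFor("water"),
                  "XLYOFNOQVPJJNP-UHFFFAOYSA-N",
                  "OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@@H]1O",
                  "WQZGKKKJIJFFOK-GASJEMHNSA-N"),
    TYPE = c("mol", "InChIKey", "SMILES", "InChIKey"),
    DIMENSION = c("2D", "1D", "1D", "1D"),
    DEFAULT_STRUCTURE = "Y", stringsAsFactors = FALSE)
  tabs
}
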