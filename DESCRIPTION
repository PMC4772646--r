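Package: chebir
Title: Local Programmatic Access to ChEBI Flat-File Releases
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An offline-capable programmatic interface to ChEBI
    (Chemical Entities of Biological Interest) release flat files.
    Provides a ChebiEntity handle exposing names, synonyms, chemical
    data (formula, mass, charge), structures (molfile, SMILES, InChI,
    InChIKey), database cross-references, literature references,
    compound origins and ontology relations for any ChEBI identifier,
    with transparent resolution of secondary (merged) identifiers to
    their primary entry. Release files are fetched on demand into a
    local cache and refreshed when stale; structure and reference
    tables are streamed from disk rather than held in memory. A
    deterministic fixture generator emits miniature, internally
    consistent releases with ground-truth manifests for offline
    testing, and a command-line interface supports entity lookup,
    relation listing, cache management and fixture generation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'instrumentation.R'
    'cache.R'
    'parsers.R'
    'streaming.R'
    'entity.R'
    'fixtures.R'
    'cli.R'
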