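---
title: "chebir: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chebir: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chebir)
```

## The problem

ChEBI publishes its content as a set of flat files updated monthly:
tab-separated tables for compounds, names, chemical data, database
cross-references, ontology relations, InChIs, comments, literature
references and biological origins, plus a quoted-CSV structures table
whose fields carry multi-line MDL molfile text. Two properties of the
data model make ad-hoc consumption error-prone. First, curation
merges duplicate entries: a deprecated record stays in the compounds
table with a `PARENT_ID` pointing at the entry that absorbed it, and
chains of such links can be more than one step deep. Any identifier
ever issued must keep resolving. Second, the full release is large
(on the order of a gigabyte decompressed), while most programs only
ever touch a small slice of it.

`chebir` addresses both: a single entity handle whose getters resolve
through the merged group, and a check–fetch–parse access path that
keeps the bulky tables on disk.

## Merged-group read semantics

For a requested identifier $r$ with primary $p$ (the fixed point of
following parent links), define the merged group $G(p)$ as $p$ plus
every compound whose parent chain terminates at $p$. The getters then
behave as follows:

* **Scalar fields** (`getName`, `getDefinition`, `getStatus`,
  `getSource`, `getCreatedBy`, `getModifiedOn`, `getStar`, the
  chemical-data and structure getters) read from the primary record,
  so a deprecated identifier answers with the curated, live values.
* **Identity fields** are the exception: `getId` echoes $r$ and
  `getParentId` the direct parent of $r$, so callers can detect
  deprecation by checking `getParentId` for a non-missing value.
* **List fields** (`getNames`, `getFormulae`,
  `getDatabaseAccessions`, `getComments`, `getCompoundOrigins`,
  `getOutgoings`, `getIncomings`, `getReferences`) return the union
  over $G(p)$, ordered primary first and then secondaries by
  ascending id, keeping file order within a member, with duplicates
  removed keeping the first occurrence. Names deduplicate on
  (name, type, language); other list getters on all returned columns.
  The rationale: a merge must not lose curated synonyms or
  cross-references that were attached to the absorbed entries, but
  the same fact recorded on both members should appear once.
* **Scalar chemical data** (`getFormula`, `getMass`, `getCharge`,
  `getMonoisotopicMass`) and structures (`getInchi`, `getInchiKey`,
  `getSmiles`, `getMol`) prefer the primary's record and fall back to
  the lowest-id group member holding one — absorbed entries sometimes
  carry data the primary lacks.

Absent values are typed `NA` (`NA_character_`, `NA_real_`,
`NA_integer_`), never empty text, so a missing charge is
distinguishable from a charge of zero. Callers that require a number
can test with `is.na()`.

Ontology relations are directed, typed edges between primary
compounds. An *outgoing* relation of entity $e$ is a row with
`INIT_ID` ∈ $G(e)$, read as $e$ —type→ target; *incoming* is the
mirror. The live release's orientation convention is not something
the flat files declare, so `parseRelease(relationDirection =
"final_outgoing")` inverts it if a release uses the opposite
convention. Relation lists are ordered by type, then target id, which
makes every list getter deterministic across runs and platforms.

## The cache

`ensureFile(logicalName, config)` implements the access path: if a
decompressed local copy exists and is fresh, it is returned with no
remote access; otherwise the file is fetched from `baseUrl`, trying
`<name>.gz`, `<name>.zip` and the plain name in that order, unpacked,
and atomically renamed into place. A failed or truncated transfer
therefore leaves either the previous valid file or nothing — never a
partial file — and a download that is not valid gzip (checked via the
magic bytes, since R's `gzfile` silently falls back to plain reading)
is removed and reported as corrupt.

Staleness is judged by **local retrieval age**: a sidecar key–value
file records when each logical file was fetched, and a file is stale
when strictly more than `maxAge` days have passed. The flat files are
updated monthly, so the default is `maxAge = 30`; the release
metadata offers no change indicator the cache could poll cheaply, and
an age policy needs no extra protocol support. The comparison is a
pure function (`isStale(record, now, maxAge)`), and both the clock
and the transport are injectable, which is how the test suite drives
the refresh logic deterministically and counts remote accesses with
`instrumentedTransport()`. With `offline = TRUE` the transport is
never invoked: present files are served regardless of age, and a
missing file raises a typed `chebi_offline_miss` error.

`baseUrl` may be a plain local directory, which the tests use as a
mock remote; nothing in the fetch path distinguishes it from an HTTP
location beyond the transport function chosen.

## Parsing and the memory contract

The nine tab-separated tables are read line-wise with explicit column
schemas: the header row is skipped, the literal token `"null"` maps
to `NA`, both LF and CRLF endings are accepted, and text is UTF-8.
Rows with the wrong column count, garbage in an integer column, or
violations of structural invariants (accession text must equal
`CHEBI:<id>`, no self-parenting) are skipped with a warning and
counted in the index's `skipped` slot; `strict = TRUE` upgrades these
to errors, and the fixture generator's output parses strictly with
zero warnings. Malformed rows never abort a whole release: a single
bad row in a million-row table should cost one record, not the
dataset. Status codes are an open single-letter vocabulary — parsing
never fails on an unseen code. Dates are kept verbatim in the index;
`getModifiedOn` parses ISO-8601 calendar dates to `Date` and returns
the raw text with a warning otherwise, so nothing is destroyed by an
unexpected format. A `columnMap` argument re-points the parser at
releases whose column order differs from the default layout.

Parent links are validated when the index is built: a `PARENT_ID`
referencing a nonexistent compound raises `chebi_dangling_parent`,
and a cycle raises `chebi_cyclic_parents` listing the cycle, so
`resolvePrimary` provably terminates on any index that constructs.

The structures and references files are the memory contract's
subject: they are never parsed into the `ChebiRelease` object, which
holds only their paths. `streamStructure()` scans the quoted CSV
through `utils::read.csv` on an open connection in chunks of 64
records (embedded newlines and doubled quotes are the standard
dialect, so the standard parser handles them), keeping only rows for
the requested compound and preferring `DEFAULT_STRUCTURE = "Y"` over
non-defaults as the tie-break; `streamReferences()` does the same for
the TSV references table. Every file open in the package is recorded
in a session log (`fileOpenLog()`), which is how the suite asserts
that constructing an entity and reading scalar fields never touches
either file. `getMolFilename` writes the streamed molfile once per
entity under the session temp directory and reuses it.

## The fixture generator

`generateFixture(fixtureSpec(...))` emits a complete miniature
release — all ten files plus gzipped variants — together with a
manifest holding every table and the expected output of every getter
for every entity, computed directly from the generator's model rather
than through the parser or entity code. The manifest is the oracle
for the whole test suite: parser round-trip tests compare the parsed
index to it field for field, and entity tests compare getter output
to its precomputed answers.

What it emulates: primary/secondary structure with parent chains up
to a configurable depth (at least one chain of depth ≥ 2 whenever the
spec allows), `"null"` sentinels, CRLF line endings (the comments
table), a multi-line molfile with embedded quotes, duplicate synonyms
shared across a merged group, signed charges over −4..+4, compounds
with and without each kind of datum, and relations connecting primary
entries only. Names and formulae are drawn from a small vocabulary of
real compound names so failures read well. Output is a deterministic
function of the spec and seed — generation runs under its own RNG
state and restores the caller's — and regenerating the flat files
from the manifest tables is byte-identical.

What it does **not** emulate: chemically valid molecules (molfiles
are a fixed three-atom template; SMILES/InChIKey are plausible-shaped
strings), the live release's scale, its exact column order (hence
`columnMap`), or its relation-orientation convention (hence
`relationDirection`). Tests passing on fixtures therefore demonstrate
the access machinery — parsing, resolution, merging, streaming,
caching — not compatibility with any particular live snapshot.

Defaults (`nPrimary = 10`, `nSecondary = 5`, `maxParentChain = 2`,
`relationDensity = 1.5`, per-table inclusion probabilities around
0.6–0.9) were chosen once to give every code path non-trivial mass in
a release small enough to generate in milliseconds; the end-to-end
checks run 20 such releases (seeds derived from one base seed),
comfortably over a thousand records in total, in a few seconds on one
CPU.

The hand-written `canonicalMiniRelease()` (water, a merged synonym
entry, D-glucose, aldohexose, one `is_a` edge) pins the documented
example values exactly and is used verbatim in the README.

## Error taxonomy and the CLI

All failure modes are classed conditions (`chebi_malformed_id`,
`chebi_undefined_id`, `chebi_offline_miss`, `chebi_fetch_failed`,
`chebi_corrupt_download`, `chebi_incomplete_release`,
`chebi_dangling_parent`, `chebi_cyclic_parents`,
`chebi_corrupt_datum`, `chebi_unsatisfiable_spec`), so callers match
on class rather than message text. The CLI (`chebiCli()`, wrapped by
`inst/cli/chebi.R`) maps them to a stable exit-code contract — 0 ok,
2 user error, 3 offline cache miss, 4 fetch failure — writes data
only to standard output and diagnostics only to standard error, and
its JSON `entity` output deserialises to exactly the library's getter
values, a property the suite asserts entity by entity. Configuration
is flags-with-defaults only; environment-variable overrides were left
out to keep the precedence story trivial.

## Known limitations

* No transitive ontology closure: `getOutgoings`/`getIncomings` are
  one hop; ancestors and descendants are the caller's recursion.
* No text search by name, and no entity depictions.
* No chemical interpretation of structures: molfiles and SMILES are
  returned verbatim, never sanitised or canonicalised.
* Staleness is local-age-based; if a release were republished within
  the `maxAge` window, the cache would serve the older copy until it
  ages out (or `purgeCache()` forces a refetch).
* The reference implementation's live column layouts are followed as
  documented here; a release that deviates needs `columnMap` or
  `relationDirection` set accordingly.
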