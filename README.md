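# chebir

Local, offline-capable programmatic access to ChEBI release flat files
from R.

ChEBI (Chemical Entities of Biological Interest) is a human-curated
database and ontology of small molecules, widely used as the source of
unambiguous chemical identifiers in metabolic models, protein and
interaction databases, metabolomics pipelines and chemical text
mining. Each entry carries names and synonyms, chemical data (formula,
mass, charge), structures (molfile, SMILES, InChI, InChIKey), database
cross-references, literature references and typed ontology relations
such as `is_a` and `has_role`. Because the database is curated,
duplicate entries are merged: a deprecated identifier is retained but
linked via a parent pointer to the primary entry that absorbed it, and
any tool consuming ChEBI identifiers has to resolve that mapping.

`chebir` hides all of this behind one handle. A `ChebiEntity` is
constructed from any identifier form (`"CHEBI:15377"`, `"15377"`,
`15377L`); secondary identifiers resolve transparently to their
primary entry, and every getter reads through the *merged group* — the
primary plus all records whose parent chains end at it. Release files
are fetched on demand into a local cache and refreshed when older
than a configurable age (default 30 days, matching the monthly release
cycle), so after one download everything works fully offline. The two
large tables — structures and literature references — are never held
in memory: they are streamed from disk in small chunks only when a
structure or reference getter is actually called.

The package also ships a deterministic fixture generator that emits
miniature, internally consistent releases together with a ground-truth
manifest (the expected output of every getter for every entity), so
the entire test suite and any downstream code can run with no network
access, plus a command-line interface for entity lookup, relation
listing, cache management and fixture generation.

## Worked example

The canonical mini-release is a fixed four-compound fixture (water, a
deprecated synonym entry merged into water, D-glucose and aldohexose)
used throughout the documentation:

```r
library(chebir)
rel <- canonicalMiniRelease()

glucose <- ChebiEntity("CHEBI:3", rel$dir)
getName(glucose)
#> [1] "D-glucose"
getFormula(glucose)
#> [1] "C6H12O6"
getCharge(glucose)
#> [1] 0
getNames(glucose)
#>              NAME       TYPE        SOURCE ADAPTED LANGUAGE
#> 1        dextrose    SYNONYM         ChEBI       F       en
#> 2     grape sugar    SYNONYM KEGG COMPOUND       F       en
#> 3 D-glucopyranose IUPAC NAME         IUPAC       F       en
getOutgoings(glucose)
#>   TYPE  TARGET STATUS
#> 1 is_a CHEBI:4      C
```

`getCharge` returning `0` is a real stored value; an entity without a
charge record returns `NA_integer_` instead, so absence is never
conflated with zero. A deprecated identifier keeps working and its
getters answer for the entry that absorbed it, while `getId`/
`getParentId` keep the deprecation visible:

```r
sec <- ChebiEntity("CHEBI:2", rel$dir)
sec
#> ChebiEntity CHEBI:2 (secondary of CHEBI:1): water
#>   formula H2O
getParentId(sec)
#> [1] "CHEBI:1"
getName(sec)     # the primary's name, not the retired record's
#> [1] "water"
getMass(sec)
#> [1] 18.0153
```

Generated fixtures behave the same way at any size:

```r
fx <- generateFixture(fixtureSpec(nPrimary = 10, nSecondary = 5, seed = 42))
loadRelease(fx$dir)
#> ChebiRelease index
#>   compounds: 15 (5 secondary, 10 merged groups)
#>   names: 27 | chemical data: 41 | accessions: 17 | relations: 15
#>   inchis: 12 | comments: 13 | origins: 5
#>   structures file: .../structures.csv
#>   references file: .../reference.tsv
```

`fx$manifest` holds the complete ground truth of the release,
including the expected value of every getter for every entity.

To work against a live flat-file area instead, build a
`cacheConfig(cacheDir, baseUrl, maxAge, offline)` and call
`releaseFromCache(cfg)`; `ensureFile()` fetches and unpacks each file
only when it is missing or stale, and `offline = TRUE` guarantees no
network access ever happens.

## Command line

```sh
Rscript inst/cli/chebi.R entity CHEBI:3 --release-dir <dir> --fields name,charge
# {"name":"D-glucose","charge":0}
Rscript inst/cli/chebi.R relations CHEBI:4 --direction in --release-dir <dir>
Rscript inst/cli/chebi.R cache status --cache-dir ~/.chebi
Rscript inst/cli/chebi.R fixture --seed 7 --n-primary 20 --out /tmp/fx
```

Data goes to standard output, diagnostics to standard error; exit
codes are 0 (ok), 2 (user error), 3 (offline cache miss), 4 (fetch
failure).

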