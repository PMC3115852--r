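# daswriteback

Community curation of protein annotations over the Distributed Annotation
System (DAS). DAS lets a client assemble positional protein features —
domains, active sites, modification sites — from many independent annotation
servers into one view, but the protocol is read-only: domain experts who
spot a wrong or missing annotation have no channel to say so. The writeback
extension adds that channel. A third-party *writeback server* accepts
creates, edits and deletions of features over plain HTTP without ever
touching the original sources, and stores every change as a new **version**
of the feature it annotates — an annotation of an annotation. Deletions are
**tombstones**: the feature is tagged deleted and its last payload retained,
so clients can still draw its outline and anyone can resurrect or audit it.

This package is a complete implementation of that protocol for R:

* **Wire format** — a reader/writer for DAS 1.6 GFF XML feature documents
  (`read_dasgff()`, `write_dasgff()`), the only format the protocol speaks
  in either direction. Coordinates are 1-based, fully closed amino-acid
  intervals; non-positional features use `start = end = 0`.
* **Store** — `wb_store()`, an append-only version log. Per feature the
  records form the contiguous chain `1..n`; `CREATE`/`UPDATE`/`DELETE`
  records are never mutated or removed, re-creation after deletion continues
  the same chain, and `rollback` appends a new version equal to an old one
  rather than rewriting history. In-memory and NDJSON-file backends sit
  behind one storage contract.
* **Service** — `wb_service()` + `dispatch_request()` map the HTTP methods
  onto the store (POST = create, PUT = update/rollback, DELETE = tombstone,
  GET = read; reads are open, writes require login and password), and
  `wb_serve()` exposes it on a TCP port via httpuv at
  `/das/writeback/features`.
* **Client** — `wb_plan()` / `fetch_annotations()` query the reference
  server, the annotation sources in order, and the writeback server strictly
  last; `wb_submit()` validates a feature locally before any network call
  and always sends write payloads in the request body (URLs can be capped at
  256 characters).
* **Merge engine** — `merge_tracks()` implements the three reading modes:
  `disabled` (originals verbatim), `extra` (writeback appended as its own
  track) and `merge` (writeback versions overwrite the originals in place;
  deleted features stay in the result flagged `DELETED` for outline
  rendering).
* **Validation** — `validate_feature()` enforces
  `1 ≤ start ≤ end ≤ sequence_length` (or `0,0`), and `suggest_terms()`
  reproduces the ontology type-ahead aid: feature types from SO/MOD/BS,
  evidence methods from ECO (small term subsets are bundled).
* **Fixtures** — deterministic generators for source documents
  (`generate_source_document()`), multi-user edit scripts
  (`generate_edit_script()`) and fully local mock federations
  (`run_mock_federation()`), so everything above is testable offline.
* **CLI** — `inst/exec/daswb` (a wrapper over `run_cli()`) with
  `serve`, `fetch`, `create`, `update`, `delete`, `rollback`, `history`,
  `merge`, `validate` and `fixtures` subcommands.

## Worked example

A mock federation with one annotation source; a community user refines one
feature and tombstones another, then the merged view is rebuilt:

```r
library(daswriteback)

uniprot <- generate_source_document(7, "P12345", sequence_length = 200, n_features = 4)
store   <- wb_store()
plan    <- run_mock_federation(list(uniprot = uniprot), store)
cred    <- list(login = "demo", password = "demo")

# refine the active site: the edit enters the writeback as version 1 of ft0002
wb_submit(plan$writeback, "create", "P12345",
          wb_feature("ft0002", type_id = "active_site", type_cvid = "SO:0000409",
                     start = 25, end = 30),
          cred, sequence_length = 200)

# tombstone ft0004: snapshot the original into the writeback, then delete
orig <- uniprot$features[uniprot$features$feature_id == "ft0004", -1]
wb_submit(plan$writeback, "create", "P12345", orig, cred, sequence_length = 200)
wb_submit(plan$writeback, "delete", "P12345", "ft0004", cred)

res <- fetch_annotations(plan, "P12345")
res$log
#> # A tibble: 3 × 3
#>   role      endpoint      ok
#>   <chr>     <chr>         <lgl>
#> 1 reference local-handler TRUE
#> 2 source    uniprot       TRUE
#> 3 writeback local-service TRUE

ts <- merge_tracks(res$originals, res$writeback, mode = "merge", segment_id = "P12345")
ts[, c("source", "feature_id", "type_id", "start", "end", "state")]
#> # A tibble: 4 × 6
#>   source  feature_id type_id                start   end state
#>   <chr>   <chr>      <chr>                  <int> <int> <chr>
#> 1 uniprot ft0001     polypeptide_motif        103   159 ORIGINAL
#> 2 uniprot ft0002     active_site               25    30 UPDATED
#> 3 uniprot ft0003     catalytic_residue         40   148 ORIGINAL
#> 4 uniprot ft0004     O4'-phospho-L-tyrosine    21   187 DELETED
```

The query log shows the federation contract (writeback last); the track set
shows the merge contract: `ft0002` now carries the community coordinates
(25–30) in place, `ft0004` is retained with its last payload but flagged
`DELETED` (a renderer draws only its border), untouched features stay
`ORIGINAL`. `autoplot(ts)` draws the tracks; `plot_feature_history()` draws
a feature's version chain. `store$feature_history("P12345", "ft0004")`
returns the full audit trail (`CREATE` then `DELETE`, versions 1–2).

To run the same thing over a real socket:

```sh
daswb serve --users users.tsv --port 8767 &
daswb create --endpoint http://127.0.0.1:8767/das/writeback/features \
      --file edit.xml --user demo --password demo
```

## Further reading

The methods vignette (`vignettes/writeback-protocol.Rmd`) documents the
protocol design: the version model and its invariants, the REST mapping and
status codes, how tombstones and histories are encoded in DAS GFF, the
validation and ontology rules, what the fixture generators do and do not
emulate, and the known limitations.
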