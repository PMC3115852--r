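---
title: "The writeback protocol: versioned community annotation over DAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The writeback protocol: versioned community annotation over DAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daswriteback)
```

## The problem and the model

The Distributed Annotation System (DAS) federates positional annotations on
biological sequences: a client queries a reference server for the sequence,
then a set of independent annotation servers for features on it, and draws
everything as tracks. The protocol is read-only. The writeback extension
adds community curation while honouring one hard constraint: *the original
sources are never modified*. All edits go to a third-party writeback server
that, for reading purposes, behaves like any other annotation server — it is
simply the last one the client queries, because an edit only makes sense
once the full annotation landscape of the protein is on screen.

The central modelling idea is **meta-annotation**: a change to an annotation
is itself an annotation. The store therefore keeps, per feature, an
append-only chain of version records:

* `CREATE` — version 1 of a feature (or a later version, when a tombstoned
  feature is resurrected);
* `UPDATE` — a new payload for a live feature, including rollbacks;
* `DELETE` — a tombstone. The feature is never physically removed; the
  record snapshots the previous payload so a client can still render its
  outline, and the feature can be re-created later.

Two invariants follow and are enforced (and property-tested) everywhere:
version numbers per `(segment, feature)` form the contiguous sequence
`1..n`, and no operation ever mutates or removes an existing record. The
*latest state* view — one row per feature, with a `deleted` flag — is by
definition the record with the highest version number, and the test suite
checks it against a naive full-scan oracle on randomized edit scripts.

The identifying key is `(segment_id, feature_id)`: DAS addresses features
within segments, and the protocol itself never states a key. A consequence,
documented rather than hidden: editing an *original* feature means writing a
version of that `feature_id` into the writeback store (the first such write
is a `CREATE` there), after which the merge engine overlays it onto the
original by id.

## REST mapping and status codes

The HTTP method carries the intent; both request and response bodies are DAS
GFF documents. The mapping follows the AtomPub/GData convention and is
isolated in a single dispatch table so it could be swapped trivially:

| method + shape                               | effect                          |
|----------------------------------------------|---------------------------------|
| `GET ?segment=S`                             | latest state of every feature   |
| `GET ?segment=S&feature=F&history=1`         | full version chain of `F`       |
| `POST` + body                                | create each feature in the body |
| `PUT` + body                                 | update each feature in the body |
| `PUT ?segment=S&feature=F&version=K`         | roll back `F` to version `K`    |
| `DELETE ?segment=S&feature=F`                | tombstone `F`                   |

Plain HTTP status codes apply: 200 success, 400 malformed or invalid, 401
unauthenticated write, 404 unknown target, 405 unknown method, 500 internal.
One deliberate addition: stale-state conflicts (creating a live feature,
writing to a tombstone) return **409** rather than 400, so a client can
distinguish "my document is broken" from "my view of the store is out of
date". Multi-feature bodies are atomic — every feature is parsed, validated
and litmus-tested for liveness *before* the first record is appended, so a
request answered with any status ≥ 400 has written nothing.

Reads are open; writes require a login/password pair (HTTP Basic over the
socket). Only salted SHA-256 digests are stored. Write payloads always
travel in the request body: DAS GFF documents routinely exceed the 256
characters some browsers and servers allow in a URL, and the client enforces
that bound on the URLs it does build.

## Encoding choices on the wire

The protocol does not say how version metadata rides inside a DAS GFF
document, so this package fixes an encoding and documents it:

* In a latest-state response each feature carries NOTE tokens
  `WRITEBACK:VERSION=n`, `WRITEBACK:USER=u`, `WRITEBACK:DATE=t` and, for
  tombstones, the literal `WRITEBACK:DELETED`. Merge engines key off the
  flag; foreign DAS clients see ordinary notes.
* A history response must not repeat a `feature_id` within a segment (a
  document invariant), so version *k* of feature `f` is serialized with id
  `f:vk` plus a `WRITEBACK:FEATURE=f` token; the client inverts this.
  The alternative — action/user/version as XML attributes — would be
  invisible to stock parsers and was rejected for that reason.
* Segments gain a `sequence_length` attribute only when it differs from
  `stop`; stock DAS clients ignore unknown attributes, and the parser
  defaults it to `stop`, so round-trips stay exact.
* Score "not applicable" is the literal `-`; encoding is fixed UTF-8; the
  serializer emits a fixed element and attribute order, so equal documents
  serialize to byte-identical text (asserted in the tests).

## Validation and ontology aids

A feature is coordinate-valid iff `1 ≤ start ≤ end ≤ sequence_length`, or
`start = end = 0` for non-positional features. "Start before end" is read as
`start ≤ end`: the strict reading would outlaw single-residue features
(phosphosites, catalytic residues), which DAS plainly requires. All
applicable issues are reported together as data (`START_AFTER_END`,
`OUT_OF_RANGE`, `NONPOSITIVE_START`, `MISSING_ID`, `BAD_ENUM`), never as a
first-failure exception; the acceptance suite checks the accepted set
exhaustively against the closed-form predicate on a 12×12 coordinate grid.

The same rules run on both sides of the wire. The client validates before
any network call; the server re-validates before any write, with one
asymmetry: the server has no reference sequence, so it validates with an
unbounded length and the protein-length check belongs to the client, which
learns the length from the reference endpoint. Orientation and phase are
genomic concepts with no meaning on proteins; they default to the DAS
"not applicable" tokens (`0`, `-`) on ingest and on the client.

Type-ahead term suggestion mirrors the annotation form: the *type* field
searches the Sequence Ontology, the protein-modification ontology (PSI-MOD)
and the BioSapiens vocabulary; the *method* field searches the Evidence Code
Ontology only. Matching is a case-insensitive prefix match on term name or
id, ranked by name with ties broken by id so the ranking is total and
deterministic. The bundled lists are small offline subsets (two-column TSV);
the BioSapiens ids are synthetic placeholders, as flagged in the file
header. Live ontology lookup services are intentionally out of scope.

## The merge engine

`merge_tracks()` implements the client's three reading modes over
`(source, feature)` tables, renderer-agnostically — deletion is a state
flag, not graphics:

* **disabled**: originals verbatim, every state `ORIGINAL`;
* **extra**: originals verbatim plus one appended `writeback` track holding
  every writeback state (tombstones flagged `DELETED`);
* **merge**: per `feature_id`, the writeback payload replaces the original
  *in place* (state `UPDATED`, or `DELETED` with the snapshot payload);
  writeback-only features are appended to the writeback track (`CREATED`).

Where the design was open, the choices are: replacement happens inside the
original source's track, with provenance carried by the state flag (moving
updated features to the writeback track would scramble the visual
correspondence with the unmerged view); the match key is `feature_id` within
the segment; and when several sources carry the same id, the first source in
input order wins with a logged warning — in merge mode the result holds at
most one entry per id. Feeding a track set back in is supported (its derived
writeback track is rebuilt), which is what makes the operation idempotent
for a fixed writeback view; the test suite asserts identity under an empty
writeback, idempotence, conservation of originals in extra mode, and
equivalence with a brute-force overlay oracle on randomized instances.

## Fixtures: what they emulate, and what they do not

Everything is testable offline through three deterministic generators.
`generate_source_document()` emulates a syntactically valid annotation
source: coordinates drawn uniformly as `start ≤ end` pairs within the
protein, types and evidence codes sampled from the bundled ontology subsets,
scores/notes/links present with fixed probabilities. Defaults (one 200-aa
segment, 10 features) are ordinary sizes for a protein feature track; the
protocol makes no distributional claims, and neither do the fixtures — they
do **not** emulate biologically realistic feature-type frequencies, overlap
structure, or inter-source correlation, so green tests certify protocol
behavior, not biological plausibility. `generate_edit_script()` emulates a
community editing session (3 users, create/update/delete/rollback with
weights 0.30/0.35/0.20/0.15, and a 25% chance that a create resurrects a
tombstone) and is replay-safe by construction: every target is live, every
rollback target exists and is not a deletion. `run_mock_federation()` wires
generated sources and a store into in-process endpoints so federation tests
open no sockets; real TCP serving (`wb_serve()`) is exercised separately
over localhost.

Sizes used by the checks: the acceptance suite runs 100 edit scripts (6–20
steps), 100 merge instances, 100 document round-trips, the 144-cell
validation grid, 20 federation plans, and one 200-step/8-user serialization
run — together they complete in about two minutes on one CPU.

## Numerical and degenerate-input notes

* Version numbers, coordinates and lengths are R integers; timestamps are
  UTC `POSIXct` assigned by an injectable server clock (tests use a
  deterministic monotone clock), with ties broken by version number.
* Scores serialize via `as.character()` (up to 15 significant digits), which
  round-trips the generated values exactly; `NA` means "not applicable".
* Unknown segments read as empty, never as errors; empty documents and
  zero-feature generations are valid; non-positional features skip range
  checks everywhere.
* Within one server process, writes are serialized through a single append
  path that assigns version numbers, so interleaved multi-user sessions
  cannot collide; the file backend assumes one writer per log file.
* `read_dasgff(check = FALSE)` admits invariant-violating documents so the
  validator (and the CLI `validate` command) can report their problems as an
  issue list instead of an opaque parse failure; the service uses the same
  lenient parse for write bodies and then re-asserts document invariants.

## Limitations

Trust or reputation ranking of users and features, distributed replication,
and conflict resolution between simultaneous edits beyond serialization are
out of scope, as are registry discovery (plans name their endpoints
explicitly), DAS sequence/structure/alignment formats, and any graphical
rendering beyond the ggplot2 sketches (`autoplot()` on track sets,
`plot_feature_history()`). Authentication is HTTP Basic; deploy behind TLS.
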