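Package: daswriteback
Title: Collaborative Protein Annotation over the Distributed Annotation System
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end implementation of the DAS writeback protocol: a
    versioned, append-only annotation store exposed as an HTTP service that
    speaks DAS GFF XML, a programmatic client that federates annotation
    sources and submits edits, a track merge engine implementing the three
    client reading modes (disabled, extra source, merge), and a validation
    layer with ontology-assisted term suggestion. Communities can create,
    edit and delete positional protein annotations without modifying the
    original annotation sources; every edit is stored as a new version of
    the feature it annotates, and deletions are tombstones, never physical
    removals. Includes deterministic fixture generators (documents, edit
    scripts, mock federations) so the whole stack is testable offline, plus
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    httpuv,
    httr,
    jsonlite,
    openssl,
    purrr,
    R6,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    xml2
Suggests:
    callr,
    curl,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
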