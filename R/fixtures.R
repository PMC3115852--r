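# Deterministic fixture generators: synthetic DAS GFF source documents,
# scripted multi-user edit sessions, and fully local mock federations, so
# every layer of the stack is testable offline. Coordinates are drawn
# uniformly as start <= end pairs within the protein; types come from the
# bundled SO/MOD/BS subsets and methods from the ECO subset. These fixtures
# emulate syntactically valid annotation traffic, not biologically realistic
# feature distributions.

with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a synthetic DAS GFF source document
#'
#' Produces a single-segment document with `n_features` features, every one
#' of which passes [validate_feature()] at the given protein length. Types
#' and ontology term ids are sampled from the bundled SO/MOD/BS subsets,
#' methods from the ECO subset. Generation is fully deterministic: the same
#' seed yields byte-identical serialized output.
#'
#' @param seed Integer seed.
#' @param segment_id Protein accession of the generated segment.
#' @param sequence_length Protein length (>= 1).
#' @param n_features Number of features (>= 0).
#' @param id_prefix Prefix of generated feature ids.
#' @return A [das_gff()] object.
#' @export
generate_source_document <- function(seed, segment_id = "P12345",
                                     sequence_length = 200L,
                                     n_features = 10L,
                                     id_prefix = "ft") {
  if (n_features < 0 || sequence_length < 1) {
    stop_input("need n_features >= 0 and sequence_length >= 1")
  }
  terms <- load_bundled_ontologies()
  type_terms <- filter(terms, .data$ontology_id %in% c("SO", "MOD", "BS"))
  eco_terms <- filter(terms, .data$ontology_id == "ECO")
  with_seed(seed, {
    feats <- map(seq_len(n_features), function(i) {
      ti <- type_terms[sample.int(nrow(type_terms), 1), ]
      mi <- eco_terms[sample.int(nrow(eco_terms), 1), ]
      pos <- sort(sample.int(sequence_length, 2, replace = TRUE))
      wb_feature(
        feature_id = sprintf("%s%04d", id_prefix, i),
        label = sprintf("%s %d", ti$term_name, i),
        type_id = ti$term_name,
        type_cvid = ti$term_id,
        type_category = tolower(ti$ontology_id),
        method_id = mi$term_name,
        method_cvid = mi$term_id,
        start = pos[1], end = pos[2],
        score = if (stats::runif(1) < 0.3) NA_real_ else
          round(stats::runif(1), 3),
        orientation = "0", phase = "-",
        notes = if (stats::runif(1) < 0.5) {
          sprintf("synthetic note %d", sample.int(1000, 1))
        } else character(),
        links = if (stats::runif(1) < 0.3) {
          tibble(href = sprintf("http://example.org/entry/%d", i),
                 label = "entry")
        } else NULL
      )
    })
    feats <- bind_rows(c(list(wb_feature_table()), feats))
    feats$segment_id <- rep(segment_id, nrow(feats))
    das_gff(
      wb_segment(segment_id, 1L, sequence_length,
                 version_label = sprintf("seed-%d", seed)),
      feats,
      source_href = sprintf("mock://%s", segment_id)
    )
  })
}

#' Generate a replayable multi-user edit script
#'
#' Simulates a community editing session: creates, updates, deletes and
#' rollbacks by `n_users` users against one segment. The script is
#' replay-safe by construction — every update/delete targets a feature that
#' is live at that point, every rollback targets an existing non-deletion
#' version — and deterministic under its seed.
#'
#' @param seed Integer seed.
#' @param n_steps Number of operations (>= 1).
#' @param n_users Number of distinct users.
#' @param segment_id,sequence_length Segment the session edits.
#' @return A `wb_edit_script`: list with `seed`, `segment_id`,
#'   `sequence_length` and a `steps` tibble (`step`, `user_id`, `op`,
#'   `feature_id`, `payload` list-column, `target_version`).
#' @export
generate_edit_script <- function(seed, n_steps = 20L, n_users = 3L,
                                 segment_id = "P12345",
                                 sequence_length = 200L) {
  stopifnot(n_steps >= 1, n_users >= 1)
  users <- sprintf("user%02d", seq_len(n_users))
  with_seed(seed, {
    # simulated chain state: per feature, the vector of actions so far
    chains <- list()
    next_id <- 1L
    new_payload <- function(fid) {
      pos <- sort(sample.int(sequence_length, 2, replace = TRUE))
      apply_protein_defaults(wb_feature(
        fid, label = sprintf("%s rev%d", fid, sample.int(100, 1)),
        type_id = "polypeptide_domain", type_cvid = "SO:0000417",
        type_category = "so",
        method_id = "experimental evidence used in manual assertion",
        method_cvid = "ECO:0000269",
        start = pos[1], end = pos[2]
      ))
    }
    steps <- map(seq_len(n_steps), function(k) {
      live <- names(chains)[map_lgl(chains, ~ utils::tail(.x, 1) != "DELETE")]
      rollbackable <- names(chains)[map_lgl(chains, function(a) {
        utils::tail(a, 1) != "DELETE" && any(a != "DELETE")
      })]
      op <- if (length(live) == 0) "create" else {
        sample(c("create", "update", "delete", "rollback"), 1,
               prob = c(0.3, 0.35, 0.2, if (length(rollbackable)) 0.15 else 0))
      }
      user <- sample(users, 1)
      if (op == "create") {
        dead <- setdiff(names(chains), live)
        fid <- if (length(dead) > 0 && stats::runif(1) < 0.25) {
          # resurrection: re-create a tombstoned feature
          sample(dead, 1)
        } else {
          id <- sprintf("wf%04d", next_id); next_id <<- next_id + 1L; id
        }
        chains[[fid]] <<- c(chains[[fid]], "CREATE")
        tibble(step = k, user_id = user, op = op, feature_id = fid,
               payload = list(new_payload(fid)), target_version = NA_integer_)
      } else if (op == "update") {
        fid <- sample(live, 1)
        chains[[fid]] <<- c(chains[[fid]], "UPDATE")
        tibble(step = k, user_id = user, op = op, feature_id = fid,
               payload = list(new_payload(fid)), target_version = NA_integer_)
      } else if (op == "delete") {
        fid <- sample(live, 1)
        chains[[fid]] <<- c(chains[[fid]], "DELETE")
        tibble(step = k, user_id = user, op = op, feature_id = fid,
               payload = list(NULL), target_version = NA_integer_)
      } else {
        fid <- sample(rollbackable, 1)
        ok <- which(chains[[fid]] != "DELETE")
        tv <- ok[sample.int(length(ok), 1)]
        chains[[fid]] <<- c(chains[[fid]], "UPDATE")
        tibble(step = k, user_id = user, op = op, feature_id = fid,
               payload = list(NULL), target_version = as.integer(tv))
      }
    })
    structure(list(seed = seed, segment_id = segment_id,
                   sequence_length = sequence_length,
                   steps = bind_rows(steps)),
              class = "wb_edit_script")
  })
}

#' Replay an edit script against a store
#'
#' @param script A `wb_edit_script` from [generate_edit_script()].
#' @param store Target [wb_store()]; a fresh in-memory store by default.
#' @return The store, invisibly, after all steps are applied.
#' @export
replay_edit_script <- function(script, store = wb_store()) {
  st <- script$steps
  for (k in seq_len(nrow(st))) {
    row <- st[k, ]
    switch(row$op,
      create = store$create_feature(script$segment_id, row$payload[[1]],
                                    row$user_id),
      update = store$update_feature(script$segment_id, row$feature_id,
                                    row$payload[[1]], row$user_id),
      delete = store$delete_feature(script$segment_id, row$feature_id,
                                    row$user_id),
      rollback = store$rollback_feature(script$segment_id, row$feature_id,
                                        row$target_version, row$user_id)
    )
  }
  invisible(store)
}

mock_source_endpoint <- function(doc) {
  force(doc)
  wb_endpoint(function(req) {
    if (req$method != "GET") {
      return(list(status = 405L, body = '{"error":"read-only source"}',
                  content_type = "application/json"))
    }
    seg <- req$query$segment
    if (is.null(seg) || !seg %in% doc$segments$segment_id) {
      return(list(status = 404L, body = '{"error":"unknown segment"}',
                  content_type = "application/json"))
    }
    list(status = 200L, body = write_dasgff(doc),
         content_type = "text/xml; charset=UTF-8")
  })
}

mock_reference_endpoint <- function(segments) {
  force(segments)
  wb_endpoint(function(req) {
    seg <- segments[segments$segment_id == (req$query$segment %||% ""), ]
    if (nrow(seg) == 0) {
      return(list(status = 404L, body = '{"error":"unknown segment"}',
                  content_type = "application/json"))
    }
    list(status = 200L, body = write_dasgff(das_gff(seg[1, ])),
         content_type = "text/xml; charset=UTF-8")
  })
}

#' Assemble a fully local mock federation
#'
#' Serves each source document from an in-process endpoint and the store
#' through the writeback service, returning a [wb_plan()] directly usable by
#' [fetch_annotations()] and [wb_submit()]. No sockets are opened, so
#' teardown is automatic; use [wb_serve()] when a real TCP endpoint is
#' needed.
#'
#' @param sources Named list of [das_gff()] documents.
#' @param store A [wb_store()] backing the writeback endpoint.
#' @param users User table for the writeback service; defaults to one
#'   account `demo`/`demo`.
#' @return A `wb_plan`.
#' @export
run_mock_federation <- function(sources, store = wb_store(),
                                users = wb_users("demo", "demo")) {
  stopifnot(length(sources) == 0 || !is.null(names(sources)))
  segs <- distinct(
    bind_rows(c(list(wb_segment("x")[0, ]), map(sources, "segments"))),
    .data$segment_id, .keep_all = TRUE)
  if (nrow(segs) == 0) segs <- wb_segment("P12345", 1L, 1L)
  wb_plan(
    reference = mock_reference_endpoint(segs),
    sources = map(sources, mock_source_endpoint),
    writeback = wb_endpoint(wb_service(store, users))
  )
}
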