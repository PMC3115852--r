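# Append-only, versioned annotation store: every write (create, update,
# delete, rollback) is itself an annotation of an annotation. Records are
# never mutated or removed; a deletion is a tombstone record that snapshots
# the prior payload so clients can still render an outline. Version numbers
# form a contiguous chain 1..n per (segment_id, feature_id), and re-creation
# after deletion continues the same chain so the audit history stays single.

ACTIONS <- c("CREATE", "UPDATE", "DELETE")

empty_records <- function() {
  tibble(
    segment_id = character(), feature_id = character(),
    version_number = integer(), action = character(),
    user_id = character(),
    timestamp = as.POSIXct(character(), tz = "UTC"),
    payload = list()
  )
}

#' In-memory storage backend
#'
#' Keeps the version log in the R session only; the backend of choice for
#' tests and ephemeral servers.
#' @return A backend object usable by [wb_store()].
#' @export
wb_backend_memory <- function() {
  structure(list(
    load = function() empty_records(),
    append = function(rec) invisible(NULL)
  ), class = "wb_backend")
}

#' File storage backend (append-only NDJSON log)
#'
#' Persists the version log as one JSON object per line. The whole log is
#' replayed when the store is opened, which is exactly the append-only
#' model: the file on disk *is* the history. Single-writer per file; writes
#' within one server process are serialized by the store.
#'
#' @param path Log file path; created on first write if absent.
#' @return A backend object usable by [wb_store()].
#' @export
wb_backend_file <- function(path) {
  structure(list(
    load = function() {
      if (!file.exists(path)) return(empty_records())
      lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
      lines <- lines[nzchar(lines)]
      bind_rows(c(list(empty_records()), map(lines, record_from_json)))
    },
    append = function(rec) {
      cat(record_to_json(rec), "\n", sep = "", file = path, append = TRUE)
      invisible(NULL)
    }
  ), class = "wb_backend")
}

feature_to_list <- function(p) {
  c(
    as.list(p[, setdiff(feature_payload_cols(), c("notes", "links"))]),
    list(notes = p$notes[[1]], links = as.list(p$links[[1]]))
  )
}

feature_from_list <- function(p) {
  wb_feature(
    feature_id = p$feature_id, label = p$label,
    type_id = p$type_id, type_cvid = p$type_cvid,
    type_category = p$type_category,
    method_id = p$method_id, method_cvid = p$method_cvid,
    start = p$start, end = p$end,
    score = if (is.null(p$score) || is.na(p$score)) NA_real_ else p$score,
    orientation = if (is.null(p$orientation)) NA_character_ else p$orientation,
    phase = if (is.null(p$phase)) NA_character_ else p$phase,
    notes = as.character(unlist(p$notes)),
    links = tibble(href = as.character(unlist(p$links$href)),
                   label = as.character(unlist(p$links$label)))
  )
}

record_to_json <- function(rec) {
  jsonlite::toJSON(list(
    segment_id = rec$segment_id, feature_id = rec$feature_id,
    version_number = rec$version_number, action = rec$action,
    user_id = rec$user_id,
    timestamp = as.numeric(rec$timestamp),
    payload = feature_to_list(rec$payload[[1]])
  ), auto_unbox = TRUE, digits = NA, null = "null", na = "null")
}

record_from_json <- function(line) {
  x <- jsonlite::fromJSON(line, simplifyVector = TRUE)
  payload <- feature_from_list(x$payload)
  tibble(
    segment_id = x$segment_id, feature_id = x$feature_id,
    version_number = as.integer(x$version_number), action = x$action,
    user_id = x$user_id,
    timestamp = as.POSIXct(x$timestamp, origin = "1970-01-01", tz = "UTC"),
    payload = list(payload)
  )
}

#' Open a writeback annotation store
#'
#' The store is the server-side heart of the writeback: a versioned,
#' append-only log of annotation edits. Its methods implement the four write
#' actions (`create_feature`, `update_feature`, `delete_feature`,
#' `rollback_feature`) and the read views (`latest_state`,
#' `feature_history`, `deleted_features`). Use [tidy()] for the flat record
#' log and [glance()] for a one-row summary.
#'
#' @param backend [wb_backend_memory()] (default) or [wb_backend_file()].
#' @param clock Zero-argument function returning the current UTC time;
#'   injectable for reproducible tests.
#' @return A `WritebackStore` R6 object.
#' @examples
#' store <- wb_store()
#' store$create_feature("P12345", wb_feature("f1", start = 3, end = 9), "ana")
#' store$latest_state("P12345")
#' @export
wb_store <- function(backend = wb_backend_memory(), clock = utc_now) {
  WritebackStore$new(backend = backend, clock = clock)
}

#' @rdname wb_store
#' @export
WritebackStore <- R6::R6Class(
  "WritebackStore",
  public = list(
    #' @param backend,clock See [wb_store()].
    initialize = function(backend = wb_backend_memory(), clock = utc_now) {
      stopifnot(inherits(backend, "wb_backend"))
      private$backend <- backend
      private$clock <- clock
      private$recs <- backend$load()
    },

    #' @description All version records, oldest first.
    records = function() private$recs,

    #' @description Append a CREATE record (version 1, or max+1 when
    #'   resurrecting a previously deleted feature).
    #' @param segment_id Segment accession.
    #' @param payload One-row feature tibble; must pass [validate_feature()].
    #' @param user_id Authenticated author login.
    create_feature = function(segment_id, payload, user_id) {
      payload <- private$check_payload(payload)
      cur <- private$latest_record(segment_id, payload$feature_id)
      if (!is.null(cur) && cur$action != "DELETE") {
        stop_conflict(sprintf(
          "feature '%s' already exists on segment '%s' and is not deleted",
          payload$feature_id, segment_id))
      }
      private$append(segment_id, payload$feature_id, "CREATE", payload, user_id)
    },

    #' @description Append an UPDATE record carrying a new payload.
    #' @param segment_id,user_id As in `create_feature`.
    #' @param feature_id Feature to update; must exist and be live.
    #' @param payload One-row feature tibble.
    update_feature = function(segment_id, feature_id, payload, user_id) {
      payload <- private$check_payload(payload)
      cur <- private$require_live(segment_id, feature_id, "updated")
      private$append(segment_id, feature_id, "UPDATE", payload, user_id)
    },

    #' @description Append a DELETE tombstone. The prior payload is
    #'   snapshotted so the feature can still be rendered as an outline.
    #' @param segment_id,feature_id,user_id Target feature and author.
    delete_feature = function(segment_id, feature_id, user_id) {
      cur <- private$require_live(segment_id, feature_id, "deleted")
      private$append(segment_id, feature_id, "DELETE", cur$payload[[1]], user_id)
    },

    #' @description Restore a historical payload by appending a new UPDATE
    #'   record whose payload equals the target version's; history is never
    #'   truncated.
    #' @param segment_id,feature_id,user_id Target feature and author.
    #' @param target_version Version whose payload to restore; must exist
    #'   and must not be a DELETE record.
    rollback_feature = function(segment_id, feature_id, target_version, user_id) {
      hist <- self$feature_history(segment_id, feature_id)
      hit <- hist[hist$version_number == target_version, ]
      if (nrow(hit) == 0) {
        stop_not_found(sprintf("version %s of '%s' does not exist",
                               target_version, feature_id))
      }
      if (hit$action == "DELETE") {
        stop_invalid_target("cannot roll back to a deletion record")
      }
      private$append(segment_id, feature_id, "UPDATE", hit$payload[[1]], user_id)
    },

    #' @description Latest state of every feature ever written on a
    #'   segment: one row per feature_id, with payload columns plus
    #'   `deleted`, `latest_version`, `last_user`, `last_timestamp`.
    #' @param segment_id Segment accession; unknown segments give zero rows.
    #' @param include_deleted Keep tombstoned features in the result?
    latest_state = function(segment_id, include_deleted = FALSE) {
      r <- private$recs[private$recs$segment_id == segment_id, ]
      if (nrow(r) == 0) return(empty_states())
      last <- r |>
        group_by(.data$feature_id) |>
        slice_max(.data$version_number, n = 1, with_ties = FALSE) |>
        ungroup()
      states <- bind_rows(last$payload)
      states <- mutate(
        states,
        segment_id = segment_id,
        deleted = last$action == "DELETE",
        latest_version = last$version_number,
        last_user = last$user_id,
        last_timestamp = last$timestamp,
        .before = 1
      )
      states <- states[, names(empty_states())]
      states <- arrange(states, .data$feature_id)
      if (!include_deleted) states <- filter(states, !.data$deleted)
      states
    },

    #' @description Full version chain of one feature, version 1 first.
    #' @param segment_id,feature_id Target feature.
    feature_history = function(segment_id, feature_id) {
      r <- private$recs[private$recs$segment_id == segment_id &
                          private$recs$feature_id == feature_id, ]
      if (nrow(r) == 0) {
        stop_not_found(sprintf("feature '%s' has no records on segment '%s'",
                               feature_id, segment_id))
      }
      arrange(r, .data$version_number)
    },

    #' @description Features whose latest record is a tombstone (the
    #'   "current deleted features" list shown in the writeback panel).
    #' @param segment_id Segment accession.
    deleted_features = function(segment_id) {
      filter(self$latest_state(segment_id, include_deleted = TRUE),
             .data$deleted)
    },

    #' @description Export the full version log as a stream of DAS GFF
    #'   documents, one per record, with WRITEBACK:* NOTE metadata.
    export_log = function() {
      map_chr(seq_len(nrow(private$recs)), function(i) {
        write_dasgff(record_document(private$recs[i, ]))
      })
    },

    #' @description Restore a store from an `export_log()` stream.
    #' @param docs Character vector of DAS GFF documents, log order.
    import_log = function(docs) {
      for (txt in docs) {
        doc <- read_dasgff(txt)
        stopifnot(nrow(doc$features) == 1)
        f <- doc$features[1, ]
        meta <- parse_writeback_notes(f$notes[[1]])
        payload <- strip_writeback_notes(f[, feature_payload_cols()])
        payload$feature_id <- meta$feature_id %||% payload$feature_id
        cur <- private$latest_record(doc$segments$segment_id[1], payload$feature_id)
        expected <- if (is.null(cur)) 1L else cur$version_number + 1L
        if (!identical(as.integer(meta$version), expected)) {
          stop_input(sprintf("log out of order: expected version %d, got %s",
                             expected, meta$version))
        }
        rec <- tibble(
          segment_id = doc$segments$segment_id[1],
          feature_id = payload$feature_id,
          version_number = expected,
          action = meta$action,
          user_id = meta$user %||% "",
          timestamp = if (is.null(meta$date)) private$clock() else parse_utc(meta$date),
          payload = list(payload)
        )
        private$recs <- bind_rows(private$recs, rec)
        private$backend$append(rec)
      }
      invisible(self)
    }
  ),
  private = list(
    backend = NULL, clock = NULL, recs = NULL,

    check_payload = function(payload) {
      # stored annotations are protein features: unset orientation/phase are
      # normalized to the DAS not-applicable tokens on ingest
      payload <- apply_protein_defaults(as_tibble(payload)[, feature_payload_cols()])
      issues <- validate_feature(payload)
      if (nrow(issues) > 0) {
        stop_validation(
          paste0("invalid feature payload: ",
                 paste(issues$code, collapse = ", ")),
          issues = issues)
      }
      payload
    },

    latest_record = function(segment_id, feature_id) {
      r <- private$recs[private$recs$segment_id == segment_id &
                          private$recs$feature_id == feature_id, ]
      if (nrow(r) == 0) return(NULL)
      r[which.max(r$version_number), ]
    },

    require_live = function(segment_id, feature_id, verb) {
      cur <- private$latest_record(segment_id, feature_id)
      if (is.null(cur)) {
        stop_not_found(sprintf("feature '%s' does not exist on segment '%s'",
                               feature_id, segment_id))
      }
      if (cur$action == "DELETE") {
        stop_conflict(sprintf(
          "feature '%s' is deleted and cannot be %s (re-create it instead)",
          feature_id, verb))
      }
      cur
    },

    # the single choke point through which every write passes: version
    # numbers are assigned here, under one method call, so concurrent users
    # multiplexed onto one server process can never collide
    append = function(segment_id, feature_id, action, payload, user_id) {
      cur <- private$latest_record(segment_id, feature_id)
      version <- if (is.null(cur)) 1L else cur$version_number + 1L
      rec <- tibble(
        segment_id = segment_id, feature_id = feature_id,
        version_number = version, action = action,
        user_id = user_id, timestamp = private$clock(),
        payload = list(payload)
      )
      private$recs <- bind_rows(private$recs, rec)
      private$backend$append(rec)
      rec
    }
  )
)

empty_states <- function() {
  st <- wb_feature_table()
  mutate(st,
         segment_id = character(), deleted = logical(),
         latest_version = integer(), last_user = character(),
         last_timestamp = as.POSIXct(character(), tz = "UTC"),
         .before = 1)
}

# one-record DAS GFF document used by export_log() and history responses
record_document <- function(rec, id_suffix = FALSE) {
  p <- rec$payload[[1]]
  meta <- c(
    sprintf("WRITEBACK:FEATURE=%s", rec$feature_id),
    sprintf("WRITEBACK:VERSION=%d", rec$version_number),
    sprintf("WRITEBACK:ACTION=%s", rec$action),
    sprintf("WRITEBACK:USER=%s", rec$user_id),
    sprintf("WRITEBACK:DATE=%s", format_utc(rec$timestamp)),
    if (rec$action == "DELETE") "WRITEBACK:DELETED"
  )
  f <- p
  if (id_suffix) {
    f$feature_id <- sprintf("%s:v%d", rec$feature_id, rec$version_number)
  }
  f$notes[[1]] <- c(f$notes[[1]], meta)
  f <- apply_protein_defaults(f)
  stop_pos <- max(1L, f$end, f$start)
  das_gff(wb_segment(rec$segment_id, 1L, stop_pos), f)
}

parse_writeback_notes <- function(notes) {
  wb <- notes[startsWith(notes, "WRITEBACK:")]
  kv <- wb[grepl("=", wb, fixed = TRUE)]
  keys <- tolower(sub("^WRITEBACK:([A-Z]+)=.*$", "\\1", kv))
  vals <- sub("^WRITEBACK:[A-Z]+=", "", kv)
  out <- as.list(stats::setNames(vals, keys))
  out$deleted <- "WRITEBACK:DELETED" %in% wb
  out$feature_id <- out$feature
  out
}

strip_writeback_notes <- function(f) {
  f$notes <- list(f$notes[[1]][!startsWith(f$notes[[1]], "WRITEBACK:")])
  f
}

#' @describeIn wb_store Flat tibble of the version log (one row per record,
#'   payload coordinates inlined).
#' @param x A `WritebackStore`.
#' @param ... Unused.
#' @export
tidy.WritebackStore <- function(x, ...) {
  r <- x$records()
  mutate(
    select(r, -"payload"),
    start = map_int(r$payload, ~ .x$start),
    end = map_int(r$payload, ~ .x$end),
    type_id = map_chr(r$payload, ~ .x$type_id)
  )
}

#' @describeIn wb_store One-row summary: record, feature, segment, live,
#'   deleted and author counts.
#' @export
glance.WritebackStore <- function(x, ...) {
  r <- x$records()
  key <- paste(r$segment_id, r$feature_id, sep = "\r")
  last <- r |>
    mutate(key = key) |>
    group_by(.data$key) |>
    slice_max(.data$version_number, n = 1, with_ties = FALSE) |>
    ungroup()
  tibble(
    n_records = nrow(r),
    n_segments = dplyr::n_distinct(r$segment_id),
    n_features = nrow(last),
    n_live = sum(last$action != "DELETE"),
    n_deleted = sum(last$action == "DELETE"),
    n_users = dplyr::n_distinct(r$user_id)
  )
}
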