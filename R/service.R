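# HTTP front-end of the writeback: REST methods map onto store operations,
# both directions speak DAS GFF, writes are gated by authentication, and
# plain HTTP status codes signal success or failure.
#
# CRUD mapping (AtomPub/GData convention), isolated here so it can be
# swapped in one place:
#   POST   + body                          -> create each feature in the body
#   PUT    + body                          -> update each feature in the body
#   PUT    ?segment=S&feature=F&version=K  -> roll back F to version K
#   DELETE ?segment=S&feature=F            -> tombstone F
#   GET    ?segment=S                      -> latest state of every feature
#   GET    ?segment=S&feature=F&history=1  -> all versions of F
#
# Statuses: 200 success, 400 malformed/invalid, 401 unauthenticated write,
# 404 unknown segment/feature/version, 405 unknown method, 409 stale-state
# conflict (create of a live feature, write to a tombstone), 500 internal.
# Deleted features in a GET response carry the NOTE token WRITEBACK:DELETED
# plus version metadata so merge engines can flag tombstones.

#' Create a writeback service
#'
#' Binds a [wb_store()] and a user table into a service object whose single
#' entry point, [dispatch_request()], maps HTTP requests to store
#' operations. [wb_serve()] exposes the same object on a TCP port.
#'
#' @param store A [wb_store()].
#' @param users User tibble from [wb_users()] or [read_users()].
#' @param log Optional function called with a one-row tibble per request
#'   (method, user, segment, feature, status) for structured logging.
#' @return A `wb_service` object.
#' @export
wb_service <- function(store, users, log = NULL) {
  structure(list(store = store, users = users, log = log),
            class = "wb_service")
}

#' Build an HTTP request for the writeback service
#'
#' @param method One of GET, PUT, POST, DELETE.
#' @param query Named list of query parameters (`segment`, `feature`,
#'   `version`, `history`).
#' @param body DAS GFF document text, or `""`.
#' @param credentials `list(login =, password =)` or `NULL`.
#' @return A `wb_request` object.
#' @export
wb_request <- function(method, query = list(), body = "", credentials = NULL) {
  structure(list(method = method, query = query, body = body,
                 credentials = credentials),
            class = "wb_request")
}

#' Dispatch one request against a writeback service
#'
#' The method/query-shape table is exhaustive and exclusive: each request
#' triggers at most one store operation, and no store write happens on any
#' request answered with a status >= 400 (multi-feature bodies are atomic —
#' all features are pre-checked before the first write).
#'
#' @param service A [wb_service()].
#' @param req A [wb_request()], or a method string (then `query`, `body`,
#'   `credentials` are used to build one).
#' @param query,body,credentials See [wb_request()].
#' @return A list with `status` (integer), `body` (text), `content_type`.
#' @examples
#' svc <- wb_service(wb_store(), wb_users("ana", "pw"))
#' doc <- das_gff(wb_segment("P12345", 1, 50), wb_feature("f1", start = 2, end = 7))
#' dispatch_request(svc, "POST", body = write_dasgff(doc),
#'                  credentials = list(login = "ana", password = "pw"))$status
#' @export
dispatch_request <- function(service, req, query = list(), body = "",
                             credentials = NULL) {
  if (!inherits(req, "wb_request")) {
    req <- wb_request(req, query = query, body = body, credentials = credentials)
  }
  res <- tryCatch(
    dispatch_impl(service, req),
    daswb_authentication_error = function(e) error_response(401L, e),
    daswb_not_found_error = function(e) error_response(404L, e),
    daswb_conflict_error = function(e) error_response(409L, e),
    daswb_invalid_target_error = function(e) error_response(400L, e),
    daswb_validation_error = function(e) error_response(400L, e),
    daswb_structural_error = function(e) error_response(400L, e),
    daswb_schema_error = function(e) error_response(400L, e),
    daswb_input_error = function(e) error_response(400L, e),
    error = function(e) error_response(500L, e)
  )
  if (is.function(service$log)) {
    service$log(tibble(
      method = req$method,
      user = req$credentials$login %||% NA_character_,
      segment = req$query$segment %||% NA_character_,
      feature = req$query$feature %||% NA_character_,
      status = res$status
    ))
  }
  res
}

error_response <- function(status, e) {
  issues <- e$issues
  payload <- list(error = conditionMessage(e))
  if (!is.null(issues)) payload$issues <- issues
  list(status = status,
       body = jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA),
       content_type = "application/json")
}

gff_response <- function(doc) {
  list(status = 200L, body = write_dasgff(doc),
       content_type = "text/xml; charset=UTF-8")
}

dispatch_impl <- function(service, req) {
  q <- req$query
  has <- function(k) !is.null(q[[k]]) && nzchar(as.character(q[[k]]))
  switch(
    req$method,
    GET = {
      if (!has("segment")) stop_input("GET requires a segment parameter")
      if (has("feature") && has("history")) {
        gff_response(history_document(service$store, q$segment, q$feature))
      } else if (!has("feature")) {
        gff_response(states_document(service$store, q$segment))
      } else {
        stop_input("GET with feature requires history=1")
      }
    },
    POST = {
      user <- authenticate_request(service, req)
      apply_write(service$store, req$body, mode = "create", user = user)
    },
    PUT = {
      user <- authenticate_request(service, req)
      if (has("segment") && has("feature") && has("version")) {
        rec <- service$store$rollback_feature(
          q$segment, q$feature, as.integer(q$version), user)
        gff_response(record_document(rec))
      } else {
        apply_write(service$store, req$body, mode = "update", user = user)
      }
    },
    DELETE = {
      user <- authenticate_request(service, req)
      if (!has("segment") || !has("feature")) {
        stop_input("DELETE requires segment and feature parameters")
      }
      rec <- service$store$delete_feature(q$segment, q$feature, user)
      gff_response(record_document(rec))
    },
    list(status = 405L,
         body = jsonlite::toJSON(list(error = "method not allowed"),
                                 auto_unbox = TRUE),
         content_type = "application/json")
  )
}

authenticate_request <- function(service, req) {
  cred <- req$credentials
  authenticate(service$users, cred$login %||% NULL, cred$password %||% NULL)
}

# atomic multi-feature write: parse, validate and pre-check liveness for
# every feature before the first store append, so a failure never leaves a
# partial write behind
apply_write <- function(store, body, mode, user) {
  if (is.null(body) || !nzchar(body)) stop_input("write request without a body")
  # parse leniently so coordinate problems surface as an issue list, not as
  # an opaque parse failure
  doc <- read_dasgff(body, check = FALSE)
  if (nrow(doc$features) == 0) stop_input("write document contains no features")
  feats <- strip_writeback_notes_all(doc$features)
  issues <- validate_feature(feats[, feature_payload_cols()])
  if (nrow(issues) > 0) {
    stop_validation("invalid feature payload(s)", issues = issues)
  }
  assert_document(doc)
  live <- map_lgl(seq_len(nrow(feats)), function(i) {
    st <- store$latest_state(feats$segment_id[i], include_deleted = TRUE)
    hit <- st[st$feature_id == feats$feature_id[i], ]
    nrow(hit) == 1 && !hit$deleted
  })
  known <- map_lgl(seq_len(nrow(feats)), function(i) {
    st <- store$latest_state(feats$segment_id[i], include_deleted = TRUE)
    feats$feature_id[i] %in% st$feature_id
  })
  if (mode == "create" && any(live)) {
    stop_conflict(sprintf("feature(s) already live: %s",
                          paste(feats$feature_id[live], collapse = ", ")))
  }
  if (mode == "update") {
    if (any(!known)) {
      stop_not_found(sprintf("unknown feature(s): %s",
                             paste(feats$feature_id[!known], collapse = ", ")))
    }
    if (any(!live)) {
      stop_conflict(sprintf("deleted feature(s) cannot be updated: %s",
                            paste(feats$feature_id[!live], collapse = ", ")))
    }
  }
  recs <- map(seq_len(nrow(feats)), function(i) {
    payload <- feats[i, feature_payload_cols()]
    if (mode == "create") {
      store$create_feature(feats$segment_id[i], payload, user)
    } else {
      store$update_feature(feats$segment_id[i], feats$feature_id[i], payload, user)
    }
  })
  docs <- map(recs, record_document)
  gff_response(combine_record_documents(docs))
}

strip_writeback_notes_all <- function(feats) {
  feats$notes <- map(feats$notes, function(n) n[!startsWith(n, "WRITEBACK:")])
  feats
}

combine_record_documents <- function(docs) {
  segs <- distinct(bind_rows(map(docs, "segments")), .data$segment_id,
                   .keep_all = TRUE)
  feats <- bind_rows(map(docs, "features"))
  stops <- feats |>
    group_by(.data$segment_id) |>
    summarise(stop = max(1L, .data$end, .data$start))
  segs <- segs |>
    select(-"stop", -"sequence_length") |>
    left_join(stops, by = "segment_id") |>
    mutate(sequence_length = .data$stop)
  das_gff(segs[, names(wb_segment("x"))], feats)
}

# GET ?segment=S: one FEATURE per feature_id ever written, tombstones marked
states_document <- function(store, segment_id) {
  st <- store$latest_state(segment_id, include_deleted = TRUE)
  if (nrow(st) == 0) {
    return(das_gff(wb_segment(segment_id, 1L, 1L)))
  }
  feats <- map(seq_len(nrow(st)), function(i) {
    f <- st[i, feature_payload_cols()]
    f$notes[[1]] <- c(f$notes[[1]],
                      sprintf("WRITEBACK:VERSION=%d", st$latest_version[i]),
                      sprintf("WRITEBACK:USER=%s", st$last_user[i]),
                      sprintf("WRITEBACK:DATE=%s", format_utc(st$last_timestamp[i])),
                      if (st$deleted[i]) "WRITEBACK:DELETED")
    f
  })
  feats <- bind_rows(feats)
  feats$segment_id <- segment_id
  stop_pos <- max(1L, feats$end, feats$start)
  das_gff(wb_segment(segment_id, 1L, stop_pos), feats)
}

# GET ?segment=S&feature=F&history=1: version k serialized with id "F:vk"
# (feature ids must stay unique within a segment) and WRITEBACK:* NOTE
# metadata carrying feature/version/action/user/date
history_document <- function(store, segment_id, feature_id) {
  hist <- store$feature_history(segment_id, feature_id)
  docs <- map(seq_len(nrow(hist)), function(i) {
    record_document(hist[i, ], id_suffix = TRUE)
  })
  combine_record_documents(docs)
}
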