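# Programmatic writeback client, mirroring the behavior of the browser
# client: annotation sources are queried in plan order and the writeback
# server strictly last (only once the full landscape of a protein is known
# does an edit make sense), and every write payload travels as a DAS GFF
# request body — never in the URL, which some browsers and servers cap at
# 256 characters.

#' Describe an endpoint of the federation
#'
#' An endpoint is either a URL (queried over HTTP) or an in-process handler
#' — a function taking a [wb_request()] and returning a response list — so
#' whole federations can be assembled and tested without sockets.
#'
#' @param x A URL string, an existing endpoint, a handler function, or a
#'   [wb_service()] (wrapped via [dispatch_request()]).
#' @return A `wb_endpoint` object.
#' @export
wb_endpoint <- function(x) {
  if (inherits(x, "wb_endpoint")) return(x)
  if (inherits(x, "wb_service")) {
    svc <- x
    return(structure(list(kind = "local",
                          handler = function(req) dispatch_request(svc, req),
                          label = "local-service"),
                     class = "wb_endpoint"))
  }
  if (is.function(x)) {
    return(structure(list(kind = "local", handler = x, label = "local-handler"),
                     class = "wb_endpoint"))
  }
  stopifnot(is.character(x), length(x) == 1)
  structure(list(kind = "http", url = x, label = x), class = "wb_endpoint")
}

endpoint_url <- function(ep, query) {
  qs <- paste(sprintf("%s=%s", names(query),
                      map_chr(query, ~ utils::URLencode(as.character(.x),
                                                        reserved = TRUE))),
              collapse = ";")
  paste0(ep$url, if (length(query)) paste0("?", qs) else "")
}

# single attempt, configurable timeout; unreachable endpoints surface as a
# classed error the caller may downgrade to skip-and-log
request_endpoint <- function(ep, method, query = list(), body = "",
                             credentials = NULL, timeout = 10) {
  if (ep$kind == "local") {
    return(ep$handler(wb_request(method, query, body, credentials)))
  }
  url <- endpoint_url(ep, query)
  if (method %in% c("PUT", "POST", "DELETE") && nchar(url) > 256) {
    stop_input(sprintf("write URL exceeds 256 characters (%d)", nchar(url)))
  }
  cfg <- list(httr::timeout(timeout))
  if (!is.null(credentials)) {
    cfg <- c(cfg, list(httr::authenticate(credentials$login,
                                          credentials$password,
                                          type = "basic")))
  }
  resp <- tryCatch(
    httr::VERB(method, url, body = if (nzchar(body)) body else NULL,
               do.call(c, cfg),
               if (nzchar(body)) httr::content_type("text/xml")),
    error = function(e) {
      wb_abort(sprintf("endpoint %s unreachable: %s", ep$label,
                       conditionMessage(e)), "unreachable_error")
    }
  )
  list(status = httr::status_code(resp),
       body = httr::content(resp, as = "text", encoding = "UTF-8"),
       content_type = httr::headers(resp)[["content-type"]] %||% "")
}

#' Define a federation plan
#'
#' The plan fixes which servers the client talks to and in which order: the
#' reference server (for the sequence length), the annotation sources in
#' display order, and the writeback server, which is always queried last.
#'
#' @param reference Endpoint of the reference server.
#' @param sources Named list of annotation-source endpoints (names become
#'   track labels).
#' @param writeback Endpoint of the writeback server.
#' @param timeout Per-request timeout in seconds.
#' @return A `wb_plan` object.
#' @export
wb_plan <- function(reference, sources, writeback, timeout = 10) {
  stopifnot(length(sources) == 0 || !is.null(names(sources)))
  structure(list(
    reference = wb_endpoint(reference),
    sources = map(sources, wb_endpoint),
    writeback = wb_endpoint(writeback),
    timeout = timeout
  ), class = "wb_plan")
}

#' Fetch a protein's annotations across the federation
#'
#' Queries the reference server, then every annotation source in plan order,
#' and the writeback server strictly last. Unreachable annotation sources
#' are logged and skipped (partial result); an unreachable writeback returns
#' the originals with an empty writeback view and a warning.
#'
#' @param plan A [wb_plan()].
#' @param segment_id Protein accession to fetch.
#' @return A list with `originals` (named list of [das_gff()]), `writeback`
#'   (latest-state tibble with `deleted`/version metadata parsed from the
#'   WRITEBACK:* NOTE tokens), `sequence_length`, and `log` — a tibble of
#'   the queries actually issued, in order (`role`, `endpoint`, `ok`).
#' @export
fetch_annotations <- function(plan, segment_id) {
  log <- list()
  note <- function(role, label, ok) {
    log[[length(log) + 1]] <<- tibble(role = role, endpoint = label, ok = ok)
  }
  q <- list(segment = segment_id)

  sequence_length <- NA_integer_
  ref <- tryCatch(
    request_endpoint(plan$reference, "GET", q, timeout = plan$timeout),
    daswb_unreachable_error = function(e) NULL)
  note("reference", plan$reference$label, !is.null(ref))
  if (!is.null(ref) && ref$status == 200) {
    rdoc <- read_dasgff(ref$body)
    hit <- rdoc$segments[rdoc$segments$segment_id == segment_id, ]
    if (nrow(hit) == 1) sequence_length <- hit$sequence_length
  }

  originals <- list()
  for (label in names(plan$sources)) {
    res <- tryCatch(
      request_endpoint(plan$sources[[label]], "GET", q, timeout = plan$timeout),
      daswb_unreachable_error = function(e) NULL)
    ok <- !is.null(res) && res$status == 200
    note("source", label, ok)
    if (ok) {
      originals[[label]] <- read_dasgff(res$body)
    } else {
      warn(sprintf("annotation source '%s' unavailable, skipped", label),
           class = "daswb_source_skipped")
    }
  }

  writeback <- empty_states()
  wres <- tryCatch(
    request_endpoint(plan$writeback, "GET", q, timeout = plan$timeout),
    daswb_unreachable_error = function(e) NULL)
  ok <- !is.null(wres) && wres$status == 200
  note("writeback", plan$writeback$label, ok)
  if (ok) {
    writeback <- parse_states_document(wres$body)
  } else {
    warn("writeback server unavailable, continuing without writeback view",
         class = "daswb_writeback_skipped")
  }

  list(originals = originals, writeback = writeback,
       sequence_length = sequence_length, log = bind_rows(log))
}

# invert states_document(): recover latest-state rows from a writeback GET
parse_states_document <- function(body) {
  doc <- read_dasgff(body)
  if (nrow(doc$features) == 0) return(empty_states())
  rows <- map(seq_len(nrow(doc$features)), function(i) {
    f <- doc$features[i, ]
    meta <- parse_writeback_notes(f$notes[[1]])
    payload <- strip_writeback_notes(f[, feature_payload_cols()])
    mutate(payload,
           segment_id = f$segment_id,
           deleted = isTRUE(meta$deleted),
           latest_version = as.integer(meta$version %||% NA_integer_),
           last_user = meta$user %||% NA_character_,
           last_timestamp = if (is.null(meta$date)) utc_now() else parse_utc(meta$date),
           .before = 1)
  })
  bind_rows(rows)[, names(empty_states())]
}

# invert history_document(): version records from a history GET
parse_history_document <- function(body) {
  doc <- read_dasgff(body)
  rows <- map(seq_len(nrow(doc$features)), function(i) {
    f <- doc$features[i, ]
    meta <- parse_writeback_notes(f$notes[[1]])
    payload <- strip_writeback_notes(f[, feature_payload_cols()])
    payload$feature_id <- meta$feature_id %||% payload$feature_id
    tibble(
      segment_id = f$segment_id,
      feature_id = payload$feature_id,
      version_number = as.integer(meta$version %||% NA_integer_),
      action = meta$action %||% NA_character_,
      user_id = meta$user %||% NA_character_,
      timestamp = if (is.null(meta$date)) utc_now() else parse_utc(meta$date),
      payload = list(payload)
    )
  })
  arrange(bind_rows(c(list(empty_records()), rows)), .data$version_number)
}

#' Submit a write operation to a writeback server
#'
#' Builds the DAS GFF body, sends it with the HTTP method the protocol maps
#' to the operation (`create` = POST, `update` = PUT, `delete` = DELETE,
#' `rollback` = PUT with a version parameter), and parses the stored version
#' metadata out of the response. For `create` and `update` the feature is
#' validated locally first — a feature the server would reject for
#' coordinate reasons never generates a request.
#'
#' @param endpoint Writeback endpoint ([wb_endpoint()], URL, or
#'   [wb_service()]).
#' @param op `"create"`, `"update"`, `"delete"` or `"rollback"`.
#' @param segment_id Protein accession.
#' @param feature One-row feature tibble (create/update); for
#'   delete/rollback, the feature id string.
#' @param credentials `list(login =, password =)`.
#' @param version Target version for `rollback`.
#' @param sequence_length Protein length used for local validation.
#' @return On success, a one-row version-record tibble; on local validation
#'   failure, the issue tibble (no request is sent), invisibly classed
#'   `wb_validation_issues`.
#' @section Errors:
#' An HTTP status >= 400 is surfaced as a `daswb_remote_error` carrying
#' `status` and the server message.
#' @export
wb_submit <- function(endpoint, op, segment_id, feature, credentials,
                      version = NULL, sequence_length = Inf) {
  endpoint <- wb_endpoint(endpoint)
  op <- match.arg(op, c("create", "update", "delete", "rollback"))
  if (op %in% c("create", "update")) {
    stopifnot(is.data.frame(feature), nrow(feature) == 1)
    feature <- apply_protein_defaults(feature)
    issues <- validate_feature(feature, sequence_length)
    if (nrow(issues) > 0) {
      return(structure(issues, class = c("wb_validation_issues", class(issues))))
    }
  }
  res <- switch(
    op,
    create = ,
    update = {
      body <- write_dasgff(das_gff(
        wb_segment(segment_id, 1L, max(1L, feature$end, feature$start)),
        feature))
      request_endpoint(endpoint, if (op == "create") "POST" else "PUT",
                       query = list(), body = body, credentials = credentials)
    },
    delete = request_endpoint(
      endpoint, "DELETE",
      query = list(segment = segment_id, feature = feature),
      credentials = credentials),
    rollback = request_endpoint(
      endpoint, "PUT",
      query = list(segment = segment_id, feature = feature,
                   version = as.integer(version)),
      credentials = credentials)
  )
  if (res$status >= 400) {
    wb_abort(sprintf("server returned %d: %s", res$status, res$body),
             "remote_error", status = res$status, server_body = res$body)
  }
  parse_history_document(res$body)
}

#' Fetch the version history of a feature from a writeback server
#'
#' @inheritParams wb_submit
#' @param feature_id Feature id.
#' @return A version-record tibble, version 1 first.
#' @export
wb_history <- function(endpoint, segment_id, feature_id) {
  endpoint <- wb_endpoint(endpoint)
  res <- request_endpoint(endpoint, "GET",
                          query = list(segment = segment_id,
                                       feature = feature_id, history = "1"))
  if (res$status >= 400) {
    wb_abort(sprintf("server returned %d: %s", res$status, res$body),
             "remote_error", status = res$status, server_body = res$body)
  }
  parse_history_document(res$body)
}
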