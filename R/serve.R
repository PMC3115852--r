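# TCP exposure of the writeback service via httpuv. The endpoint is
# /das/writeback/features; query keys segment, feature, version, history;
# credentials travel as HTTP Basic authentication. Write payloads always
# travel in the request body, never the URL (some browsers and servers cap
# URLs at 256 characters, far too small for a DAS GFF document).

WB_PATH <- "/das/writeback/features"

parse_query_string <- function(qs) {
  qs <- sub("^\\?", "", qs %||% "")
  if (!nzchar(qs)) return(list())
  parts <- strsplit(qs, "[;&]")[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- map_chr(kv, function(x) {
    httpuv::decodeURIComponent(if (length(x) < 2) "" else x[2])
  })
  stats::setNames(as.list(vals), map_chr(kv, 1))
}

parse_basic_auth <- function(header) {
  if (is.null(header) || !grepl("^Basic ", header)) return(NULL)
  dec <- tryCatch(
    rawToChar(jsonlite::base64_dec(sub("^Basic ", "", header))),
    error = function(e) NULL)
  if (is.null(dec) || !grepl(":", dec, fixed = TRUE)) return(NULL)
  at <- regexpr(":", dec, fixed = TRUE)
  list(login = substr(dec, 1, at - 1), password = substr(dec, at + 1, nchar(dec)))
}

rook_app <- function(service) {
  list(call = function(req) {
    path <- req$PATH_INFO %||% ""
    if (path != WB_PATH) {
      return(list(status = 404L,
                  headers = list("Content-Type" = "application/json"),
                  body = '{"error":"unknown path"}'))
    }
    body <- ""
    if (!is.null(req$rook.input)) {
      raw <- req$rook.input$read()
      if (length(raw) > 0) body <- rawToChar(raw)
    }
    res <- dispatch_request(
      service,
      wb_request(
        method = req$REQUEST_METHOD,
        query = parse_query_string(req$QUERY_STRING),
        body = body,
        credentials = parse_basic_auth(req$HTTP_AUTHORIZATION)
      )
    )
    list(status = res$status,
         headers = list("Content-Type" = res$content_type),
         body = as.character(res$body))
  })
}

#' Serve a writeback service over HTTP
#'
#' Starts an httpuv server exposing the service at
#' `/das/writeback/features`. Returns the server handle; stop it with
#' [wb_serve_stop()]. Use `blocking = TRUE` (the CLI `serve` command does)
#' to run the event loop in the foreground.
#'
#' @param service A [wb_service()].
#' @param host Bind address.
#' @param port TCP port.
#' @param blocking Run the event loop until interrupted?
#' @return The httpuv server handle (invisibly when blocking).
#' @section Errors:
#' A port that cannot be bound signals a `daswb_startup_error`.
#' @export
wb_serve <- function(service, host = "127.0.0.1", port = 8767, blocking = FALSE) {
  srv <- tryCatch(
    httpuv::startServer(host, port, rook_app(service)),
    error = function(e) {
      wb_abort(sprintf("cannot bind %s:%d: %s", host, port, conditionMessage(e)),
               "startup_error")
    }
  )
  if (blocking) {
    on.exit(httpuv::stopServer(srv), add = TRUE)
    inform(sprintf("writeback service listening on http://%s:%d%s",
                   host, port, WB_PATH))
    while (TRUE) {
      httpuv::service(250)
    }
  }
  srv
}

#' @rdname wb_serve
#' @param server Handle returned by `wb_serve()`.
#' @export
wb_serve_stop <- function(server) {
  httpuv::stopServer(server)
  invisible(NULL)
}
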