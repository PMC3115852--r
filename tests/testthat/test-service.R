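# REST dispatch: method/effect table, status codes, authentication gating,
# and atomicity of multi-feature writes.

post_doc <- function(svc, doc, cred = demo_credentials) {
  dispatch_request(svc, "POST", body = write_dasgff(doc), credentials = cred)
}

test_that("the scripted CRUD lifecycle returns the protocol's status codes", {
  svc <- demo_service()
  doc <- demo_doc()

  res <- post_doc(svc, doc)
  expect_equal(res$status, 200L)
  stored <- read_dasgff(res$body)
  expect_true("WRITEBACK:VERSION=1" %in% stored$features$notes[[1]])

  res <- dispatch_request(svc, "GET", query = list(segment = "P12345"))
  expect_equal(res$status, 200L)
  expect_equal(read_dasgff(res$body)$features$feature_id, "f1")

  upd <- das_gff(wb_segment("P12345", 1, 100), demo_feature(start = 15, end = 30))
  res <- dispatch_request(svc, "PUT", body = write_dasgff(upd),
                          credentials = demo_credentials)
  expect_equal(res$status, 200L)
  expect_true("WRITEBACK:VERSION=2" %in% read_dasgff(res$body)$features$notes[[1]])

  res <- dispatch_request(svc, "DELETE",
                          query = list(segment = "P12345", feature = "f1"),
                          credentials = demo_credentials)
  expect_equal(res$status, 200L)

  res <- dispatch_request(svc, "GET", query = list(segment = "P12345"))
  expect_equal(res$status, 200L)
  notes <- read_dasgff(res$body)$features$notes[[1]]
  expect_true("WRITEBACK:DELETED" %in% notes)
  expect_true("WRITEBACK:VERSION=3" %in% notes)
})

test_that("each method/query shape maps to exactly one effect", {
  svc <- demo_service()
  post_doc(svc, demo_doc())
  cred <- demo_credentials
  cases <- list(
    list("GET", list(), "", NULL, 400L),                      # no segment
    list("GET", list(segment = "P12345"), "", NULL, 200L),
    list("GET", list(segment = "P12345", feature = "f1"), "", NULL, 400L),
    list("GET", list(segment = "P12345", feature = "f1", history = "1"),
         "", NULL, 200L),
    list("POST", list(), "", cred, 400L),                     # no body
    list("PUT", list(), "", cred, 400L),
    list("DELETE", list(segment = "P12345"), "", cred, 400L), # no feature
    list("DELETE", list(feature = "f1"), "", cred, 400L),
    list("OPTIONS", list(), "", NULL, 405L),
    list("HEAD", list(segment = "P12345"), "", NULL, 405L)
  )
  for (cs in cases) {
    res <- dispatch_request(svc, cs[[1]], query = cs[[2]], body = cs[[3]],
                            credentials = cs[[4]])
    expect_equal(res$status, cs[[5]],
                 label = sprintf("%s %s", cs[[1]], paste(names(cs[[2]]), collapse = ",")))
  }
})

test_that("writes without valid credentials are 401 and leave no trace", {
  store <- wb_store(clock = test_clock())
  svc <- wb_service(store, wb_users("ana", "s3cret"))
  doc <- demo_doc()
  body <- write_dasgff(doc)
  before <- nrow(store$records())

  for (cred in list(NULL, list(login = "ana", password = "wrong"),
                    list(login = "ghost", password = "x"),
                    list(login = "", password = ""))) {
    expect_equal(dispatch_request(svc, "POST", body = body,
                                  credentials = cred)$status, 401L)
    expect_equal(dispatch_request(svc, "PUT", body = body,
                                  credentials = cred)$status, 401L)
    expect_equal(dispatch_request(svc, "DELETE",
                                  query = list(segment = "P12345", feature = "f1"),
                                  credentials = cred)$status, 401L)
  }
  expect_equal(nrow(store$records()), before)
  # reads never require credentials
  expect_equal(dispatch_request(svc, "GET",
                                query = list(segment = "P12345"))$status, 200L)
})

test_that("authenticate verifies the salted digest, never the clear password", {
  users <- wb_users(c("ana", "ben"), c("s3cret", "pa55"))
  expect_false(any(grepl("s3cret", unlist(users), fixed = TRUE)))
  expect_equal(authenticate(users, "ana", "s3cret"), "ana")
  expect_error(authenticate(users, "ana", "pa55"),
               class = "daswb_authentication_error")
  expect_error(authenticate(users, "nobody", "s3cret"),
               class = "daswb_authentication_error")
  expect_error(authenticate(users, NULL, NULL),
               class = "daswb_authentication_error")
})

test_that("multi-feature bodies are atomic: all or nothing", {
  store <- wb_store(clock = test_clock())
  svc <- wb_service(store, wb_users("ana", "s3cret"))
  good2 <- das_gff(wb_segment("P12345", 1, 100),
                   dplyr::bind_rows(demo_feature("a1", 1, 5),
                                    demo_feature("a2", 6, 9)))
  expect_equal(post_doc(svc, good2)$status, 200L)
  expect_equal(nrow(store$records()), 2)

  # one feature of the next document conflicts: nothing must be written
  conflict <- das_gff(wb_segment("P12345", 1, 100),
                      dplyr::bind_rows(demo_feature("a3", 1, 5),
                                       demo_feature("a1", 6, 9)))
  expect_equal(post_doc(svc, conflict)$status, 409L)
  expect_equal(nrow(store$records()), 2)
  expect_false("a3" %in% store$latest_state("P12345")$feature_id)

  # malformed payloads are rejected with a machine-readable issue list
  bad_xml <- paste0(
    '<DASGFF><GFF href=""><SEGMENT id="P12345" start="1" stop="100">',
    '<FEATURE id="a4"><START>1</START><END>5</END></FEATURE>',
    '<FEATURE id="a5"><START>9</START><END>2</END></FEATURE>',
    '</SEGMENT></GFF></DASGFF>')
  res <- dispatch_request(svc, "POST", body = bad_xml,
                          credentials = list(login = "ana", password = "s3cret"))
  expect_equal(res$status, 400L)
  parsed <- jsonlite::fromJSON(res$body)
  expect_true("START_AFTER_END" %in% parsed$issues$code)
  expect_equal(nrow(store$records()), 2)
  # truncated XML is a 400 too
  expect_equal(dispatch_request(svc, "POST", body = substr(bad_xml, 1, 60),
                                credentials = list(login = "ana", password = "s3cret"))$status,
               400L)
})

test_that("a document accepted by POST is returned by GET modulo version notes", {
  svc <- demo_service()
  doc <- generate_source_document(31, "P12345", 100, 3)
  expect_equal(post_doc(svc, doc)$status, 200L)
  res <- dispatch_request(svc, "GET", query = list(segment = "P12345"))
  got <- read_dasgff(res$body)$features
  got$notes <- purrr::map(got$notes, ~ .x[!startsWith(.x, "WRITEBACK:")])
  got <- got[match(doc$features$feature_id, got$feature_id), ]
  expect_true(features_equal(got[, -1], doc$features[, -1]))
})

test_that("rollback is a PUT with segment, feature and version", {
  svc <- demo_service()
  post_doc(svc, demo_doc())
  upd <- das_gff(wb_segment("P12345", 1, 100), demo_feature(start = 40, end = 60))
  dispatch_request(svc, "PUT", body = write_dasgff(upd),
                   credentials = demo_credentials)
  res <- dispatch_request(svc, "PUT",
                          query = list(segment = "P12345", feature = "f1",
                                       version = "1"),
                          credentials = demo_credentials)
  expect_equal(res$status, 200L)
  back <- read_dasgff(res$body)$features
  expect_equal(back$start, 10L)  # version 1 coordinates restored
  expect_true("WRITEBACK:VERSION=3" %in% back$notes[[1]])
  # unknown version and tombstone targets fail without writing
  expect_equal(dispatch_request(svc, "PUT",
                                query = list(segment = "P12345", feature = "f1",
                                             version = "9"),
                                credentials = demo_credentials)$status, 404L)
})

test_that("unknown targets give 404, reads of unknown segments an empty document", {
  svc <- demo_service()
  expect_equal(dispatch_request(svc, "DELETE",
                                query = list(segment = "P12345", feature = "nope"),
                                credentials = demo_credentials)$status, 404L)
  res <- dispatch_request(svc, "GET", query = list(segment = "EMPTY"))
  expect_equal(res$status, 200L)
  expect_equal(nrow(read_dasgff(res$body)$features), 0)
  expect_equal(dispatch_request(svc, "GET",
                                query = list(segment = "P12345", feature = "x",
                                             history = "1"))$status, 404L)
})

test_that("the request log records method, user, segment and status", {
  entries <- list()
  store <- wb_store(clock = test_clock())
  svc <- wb_service(store, wb_users("ana", "s3cret"),
                    log = function(e) entries[[length(entries) + 1]] <<- e)
  dispatch_request(svc, "GET", query = list(segment = "P12345"))
  post_doc(svc, demo_doc(), cred = list(login = "ana", password = "s3cret"))
  log <- dplyr::bind_rows(entries)
  expect_equal(log$method, c("GET", "POST"))
  expect_equal(log$status, c(200L, 200L))
  expect_equal(log$user[2], "ana")
})
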