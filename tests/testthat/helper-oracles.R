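# Independent brute-force oracles the property tests compare against. These
# are deliberately naive (plain loops over plain lists) and share no code
# with the implementations they check.

# latest state per feature by scanning every record and keeping the max
# version; returns a plain data.frame of (feature_id, version, action, user)
oracle_latest <- function(records) {
  out <- list()
  for (i in seq_len(nrow(records))) {
    fid <- records$feature_id[i]
    v <- records$version_number[i]
    if (is.null(out[[fid]]) || v > out[[fid]]$version) {
      out[[fid]] <- list(version = v, action = records$action[i],
                         user = records$user_id[i],
                         payload = records$payload[[i]])
    }
  }
  out
}

oracle_live_ids <- function(records) {
  st <- oracle_latest(records)
  sort(names(st)[vapply(st, function(x) x$action != "DELETE", logical(1))])
}

oracle_deleted_ids <- function(records) {
  st <- oracle_latest(records)
  sort(names(st)[vapply(st, function(x) x$action == "DELETE", logical(1))])
}

# brute-force merge overlay: build a feature_id -> writeback-state map, walk
# the originals substituting and flagging, then append leftovers
oracle_merge <- function(originals, writeback, segment_id) {
  wbmap <- list()
  for (i in seq_len(nrow(writeback))) {
    wbmap[[writeback$feature_id[i]]] <- writeback[i, ]
  }
  rows <- list()
  seen <- character()
  for (label in names(originals)) {
    feats <- originals[[label]]$features
    for (i in seq_len(nrow(feats))) {
      f <- feats[i, ]
      if (f$feature_id %in% seen) next  # first source wins
      seen <- c(seen, f$feature_id)
      w <- wbmap[[f$feature_id]]
      if (is.null(w)) {
        rows[[length(rows) + 1]] <- list(source = label, id = f$feature_id,
                                         start = f$start, end = f$end,
                                         state = "ORIGINAL")
      } else {
        rows[[length(rows) + 1]] <- list(
          source = label, id = f$feature_id, start = w$start, end = w$end,
          state = if (w$deleted) "DELETED" else "UPDATED")
      }
    }
  }
  for (fid in names(wbmap)) {
    if (fid %in% seen) next
    w <- wbmap[[fid]]
    rows[[length(rows) + 1]] <- list(
      source = "writeback", id = fid, start = w$start, end = w$end,
      state = if (w$deleted) "DELETED" else "CREATED")
  }
  do.call(rbind, lapply(rows, as.data.frame))
}

trackset_as_plain <- function(ts) {
  data.frame(source = ts$source, id = ts$feature_id,
             start = ts$start, end = ts$end, state = ts$state,
             stringsAsFactors = FALSE)
}

# deterministic test clock: strictly increasing, seeded at a fixed instant
test_clock <- function() {
  t0 <- as.POSIXct("2011-05-10 12:00:00", tz = "UTC")
  n <- 0
  function() {
    n <<- n + 1
    t0 + n
  }
}

demo_credentials <- list(login = "ana", password = "s3cret")

demo_service <- function(store = wb_store(clock = test_clock())) {
  wb_service(store, wb_users(c("ana", "ben"), c("s3cret", "pa55")))
}

demo_feature <- function(id = "f1", start = 10L, end = 20L, ...) {
  wb_feature(id, type_id = "polypeptide_domain", type_cvid = "SO:0000417",
             type_category = "so",
             method_id = "experimental evidence used in manual assertion",
             method_cvid = "ECO:0000269", start = start, end = end, ...)
}

demo_doc <- function(segment = "P12345", length = 100L, ...) {
  das_gff(wb_segment(segment, 1L, length), demo_feature(...))
}
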