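# Versioned, append-only annotation store: version chains, tombstones,
# rollback, and oracle equivalence of the read views.

test_that("the create/update/delete lifecycle builds one contiguous chain", {
  store <- wb_store(clock = test_clock())
  r1 <- store$create_feature("P12345", demo_feature(), "ana")
  expect_equal(r1$version_number, 1L)
  expect_equal(r1$action, "CREATE")

  r2 <- store$update_feature("P12345", "f1", demo_feature(start = 12, end = 25), "ben")
  expect_equal(r2$version_number, 2L)
  st <- store$latest_state("P12345")
  expect_equal(st$start, 12L)
  expect_equal(st$end, 25L)
  expect_equal(st$last_user, "ben")

  r3 <- store$delete_feature("P12345", "f1", "ana")
  expect_equal(r3$version_number, 3L)
  st <- store$latest_state("P12345", include_deleted = TRUE)
  expect_true(st$deleted)
  expect_equal(st$latest_version, 3L)
  # the tombstone snapshots the prior payload so an outline stays renderable
  expect_equal(st$start, 12L)
  expect_equal(store$latest_state("P12345")$feature_id, character(0))
  expect_equal(store$deleted_features("P12345")$feature_id, "f1")
})

test_that("re-creation after deletion continues the same version chain", {
  store <- wb_store(clock = test_clock())
  store$create_feature("P12345", demo_feature(), "ana")
  store$update_feature("P12345", "f1", demo_feature(start = 2, end = 4), "ana")
  store$delete_feature("P12345", "f1", "ana")
  r4 <- store$create_feature("P12345", demo_feature(start = 7, end = 9), "ben")
  expect_equal(r4$version_number, 4L)
  expect_equal(r4$action, "CREATE")
  expect_false("f1" %in% store$deleted_features("P12345")$feature_id)
  hist <- store$feature_history("P12345", "f1")
  expect_equal(hist$action, c("CREATE", "UPDATE", "DELETE", "CREATE"))
  expect_equal(hist$version_number, 1:4)
})

test_that("conflicting or impossible writes are refused with classed errors", {
  store <- wb_store(clock = test_clock())
  store$create_feature("P12345", demo_feature(), "ana")
  expect_error(store$create_feature("P12345", demo_feature(), "ben"),
               class = "daswb_conflict_error")
  expect_error(store$update_feature("P12345", "ghost", demo_feature("ghost"), "ana"),
               class = "daswb_not_found_error")
  expect_error(store$delete_feature("P12345", "ghost", "ana"),
               class = "daswb_not_found_error")
  store$delete_feature("P12345", "f1", "ana")
  expect_error(store$delete_feature("P12345", "f1", "ana"),
               class = "daswb_conflict_error")
  expect_error(store$update_feature("P12345", "f1", demo_feature(), "ana"),
               class = "daswb_conflict_error")
  expect_error(store$create_feature("P12345", wb_feature("bad", start = 9, end = 2), "ana"),
               class = "daswb_validation_error")
})

test_that("rollback restores the target payload as a new version", {
  store <- wb_store(clock = test_clock())
  store$create_feature("P12345", demo_feature(start = 1, end = 5), "ana")
  store$update_feature("P12345", "f1", demo_feature(start = 2, end = 6), "ana")
  store$update_feature("P12345", "f1", demo_feature(start = 3, end = 7), "ben")
  store$update_feature("P12345", "f1", demo_feature(start = 4, end = 8), "ben")
  r5 <- store$rollback_feature("P12345", "f1", 2L, "ana")
  expect_equal(r5$version_number, 5L)
  expect_equal(r5$action, "UPDATE")
  hist <- store$feature_history("P12345", "f1")
  expect_equal(nrow(hist), 5)
  expect_true(all(diff(hist$version_number) == 1))
  expect_true(features_equal(hist$payload[[5]], hist$payload[[2]]))

  expect_error(store$rollback_feature("P12345", "f1", 9L, "ana"),
               class = "daswb_not_found_error")
  store$delete_feature("P12345", "f1", "ana")
  store$create_feature("P12345", demo_feature(), "ana")
  expect_error(store$rollback_feature("P12345", "f1", 6L, "ana"),
               class = "daswb_invalid_target_error")  # v6 is the tombstone
})

test_that("read views agree with a naive full-scan oracle on random scripts", {
  for (seed in 1:30) {
    store <- wb_store(clock = test_clock())
    script <- generate_edit_script(seed, n_steps = 12L, n_users = 3L)
    replay_edit_script(script, store)
    recs <- store$records()

    expect_equal(store$latest_state(script$segment_id)$feature_id,
                 oracle_live_ids(recs))
    expect_equal(store$deleted_features(script$segment_id)$feature_id,
                 oracle_deleted_ids(recs))
    st <- oracle_latest(recs)
    view <- store$latest_state(script$segment_id, include_deleted = TRUE)
    for (i in seq_len(nrow(view))) {
      o <- st[[view$feature_id[i]]]
      expect_equal(view$latest_version[i], o$version)
      expect_equal(view$last_user[i], o$user)
      expect_true(features_equal(view[i, names(wb_feature_table())], o$payload))
    }
    # version chains are contiguous from 1 per feature
    for (fid in unique(recs$feature_id)) {
      v <- sort(recs$version_number[recs$feature_id == fid])
      expect_equal(v, seq_along(v))
    }
  }
})

test_that("the store is append-only: no operation rewrites history", {
  store <- wb_store(clock = test_clock())
  script <- generate_edit_script(5, n_steps = 15L, n_users = 2L)
  n_before <- 0L
  for (k in seq_len(nrow(script$steps))) {
    replay_edit_script(
      structure(list(seed = 5, segment_id = script$segment_id,
                     sequence_length = script$sequence_length,
                     steps = script$steps[k, ]), class = "wb_edit_script"),
      store)
    recs <- store$records()
    expect_equal(nrow(recs), n_before + 1L)
    n_before <- nrow(recs)
  }
  # unknown segments read as empty, never as an error
  expect_equal(nrow(store$latest_state("NOPE")), 0)
  expect_equal(nrow(store$deleted_features("NOPE")), 0)
  expect_error(store$feature_history("NOPE", "f1"), class = "daswb_not_found_error")
})

test_that("every record carries the authenticated author", {
  store <- wb_store(clock = test_clock())
  script <- generate_edit_script(8, n_steps = 20L, n_users = 4L)
  replay_edit_script(script, store)
  expect_identical(store$records()$user_id, script$steps$user_id)
})

test_that("the file backend replays its log into an identical store", {
  path <- withr::local_tempfile(fileext = ".ndjson")
  store <- wb_store(wb_backend_file(path), clock = test_clock())
  replay_edit_script(generate_edit_script(13, n_steps = 18L, n_users = 3L), store)
  reopened <- wb_store(wb_backend_file(path))
  a <- store$records(); b <- reopened$records()
  expect_equal(a[, c("segment_id", "feature_id", "version_number", "action", "user_id")],
               b[, c("segment_id", "feature_id", "version_number", "action", "user_id")])
  expect_equal(as.numeric(a$timestamp), as.numeric(b$timestamp))
  for (i in seq_len(nrow(a))) {
    expect_true(features_equal(a$payload[[i]], b$payload[[i]]))
  }
})

test_that("the version log exports and re-imports as a DAS GFF stream", {
  store <- wb_store(clock = test_clock())
  replay_edit_script(generate_edit_script(21, n_steps = 10L, n_users = 2L), store)
  stream <- store$export_log()
  expect_length(stream, nrow(store$records()))
  restored <- wb_store()
  restored$import_log(stream)
  a <- store$records(); b <- restored$records()
  expect_equal(a[, c("segment_id", "feature_id", "version_number", "action", "user_id")],
               b[, c("segment_id", "feature_id", "version_number", "action", "user_id")])
})

test_that("tidy and glance summarise the log", {
  store <- wb_store(clock = test_clock())
  replay_edit_script(generate_edit_script(3, n_steps = 9L, n_users = 2L), store)
  td <- tidy(store)
  expect_equal(nrow(td), 9)
  expect_true(all(c("action", "user_id", "start", "end") %in% names(td)))
  g <- glance(store)
  expect_equal(g$n_records, 9L)
  expect_equal(g$n_features, g$n_live + g$n_deleted)
})
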