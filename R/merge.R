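# Client-side reading modes: how the writeback view is combined with the
# original annotation sources. Three modes, as in the client UI:
#   disabled — writeback ignored, originals shown verbatim;
#   extra    — originals verbatim plus one appended "writeback" track;
#   merge    — writeback annotations overwrite the originals in place;
#              tombstoned features stay in the result flagged DELETED (a
#              renderer draws them transparent with only the border), and
#              writeback-only features are appended to the writeback track.
# This module is renderer-agnostic: deletion is a state flag, not graphics.

TRACK_STATES <- c("ORIGINAL", "CREATED", "UPDATED", "DELETED")
WRITEBACK_TRACK <- "writeback"

#' Merge original annotation tracks with the writeback view
#'
#' Combines per-source DAS GFF documents with the latest writeback states of
#' a segment under one of the three reading modes. The match key between an
#' original feature and a writeback state is the `feature_id` within the
#' segment; when several sources carry the same id, the first source in
#' input order wins and a warning is logged.
#'
#' The result is a track set: one row per displayed feature, with `source`,
#' the feature payload columns, and a provenance `state` (ORIGINAL, CREATED,
#' UPDATED or DELETED). Passing a track set back in as `originals` is
#' supported (its derived `writeback` track is rebuilt), which makes the
#' operation idempotent for a fixed writeback view. The source label
#' `"writeback"` is reserved.
#'
#' @param originals Named list of [das_gff()] documents (names are source
#'   labels), or a track set from a previous call.
#' @param writeback Latest-state tibble for the segment, as returned by
#'   `store$latest_state(segment_id, include_deleted = TRUE)` or
#'   [fetch_annotations()].
#' @param mode `"disabled"`, `"extra"` or `"merge"`.
#' @param segment_id Segment all inputs must address.
#' @return A `wb_trackset` tibble.
#' @examples
#' doc <- das_gff(wb_segment("P12345", 1, 60), wb_feature("f1", start = 5, end = 9))
#' merge_tracks(list(uniprot = doc), mode = "disabled", segment_id = "P12345")
#' @export
merge_tracks <- function(originals, writeback = empty_states(),
                         mode = c("disabled", "extra", "merge"),
                         segment_id) {
  mode <- match.arg(mode)
  tracks <- as_track_table(originals, segment_id)
  writeback <- as_tibble(writeback)
  if (nrow(writeback) > 0 && any(writeback$segment_id != segment_id)) {
    stop_input("writeback states address a different segment")
  }

  out <- switch(
    mode,
    disabled = mutate(tracks, state = "ORIGINAL"),
    extra = bind_rows(
      mutate(tracks, state = "ORIGINAL"),
      extra_writeback_track(tracks, writeback)
    ),
    merge = merge_overlay(tracks, writeback)
  )
  structure(out[, trackset_cols()], class = c("wb_trackset", class(out)))
}

trackset_cols <- function() c("source", "segment_id", feature_payload_cols(), "state")

# normalize the originals argument to (source, segment_id, payload...) rows;
# a track-set input contributes its non-derived tracks
as_track_table <- function(originals, segment_id) {
  if (is.data.frame(originals)) {
    tracks <- filter(as_tibble(originals), .data$source != WRITEBACK_TRACK)
    return(tracks[, c("source", "segment_id", feature_payload_cols())])
  }
  if (length(originals) > 0 && is.null(names(originals))) {
    stop_input("originals must be a named list of documents")
  }
  rows <- imap(originals, function(doc, label) {
    if (!segment_id %in% doc$segments$segment_id) {
      stop_input(sprintf("source '%s' does not address segment '%s'",
                         label, segment_id))
    }
    feats <- filter(doc$features, .data$segment_id == !!segment_id)
    mutate(feats, source = !!label, .before = 1)
  })
  empty <- mutate(wb_feature_table(), source = character(),
                  segment_id = character(), .before = 1)
  bind_rows(c(list(empty), rows))[, c("source", "segment_id", feature_payload_cols())]
}

wb_states_as_entries <- function(writeback) {
  entries <- writeback[, c("segment_id", feature_payload_cols())]
  mutate(entries, source = WRITEBACK_TRACK, .before = 1)
}

extra_writeback_track <- function(tracks, writeback) {
  if (nrow(writeback) == 0) return(NULL)
  entries <- wb_states_as_entries(writeback)
  entries$state <- dplyr::case_when(
    writeback$deleted ~ "DELETED",
    writeback$feature_id %in% tracks$feature_id ~ "UPDATED",
    .default = "CREATED"
  )
  entries
}

merge_overlay <- function(tracks, writeback) {
  # the merge invariant allows at most one entry per feature_id across all
  # tracks: duplicate ids across sources collapse to the first source in
  # input order
  dup <- duplicated(tracks$feature_id)
  if (any(dup)) {
    warn(sprintf("duplicate feature id(s) across sources, keeping first: %s",
                 paste(unique(tracks$feature_id[dup]), collapse = ", ")),
         class = "daswb_duplicate_ids")
    tracks <- tracks[!dup, ]
  }
  wb_idx <- match(tracks$feature_id, writeback$feature_id)
  out <- tracks
  out$state <- "ORIGINAL"
  for (i in which(!is.na(wb_idx))) {
    w <- writeback[wb_idx[i], ]
    repl <- w[, feature_payload_cols()]
    out[i, feature_payload_cols()] <- repl
    out$state[i] <- if (w$deleted) "DELETED"
      else if (out$source[i] == WRITEBACK_TRACK) "CREATED"
      else "UPDATED"
  }
  leftovers <- writeback[!writeback$feature_id %in% tracks$feature_id, ]
  if (nrow(leftovers) > 0) {
    extra <- wb_states_as_entries(leftovers)
    extra$state <- ifelse(leftovers$deleted, "DELETED", "CREATED")
    out <- bind_rows(out, extra)
  }
  out
}

#' Write a track set as an annotated DAS GFF document
#'
#' Serializes a merged view back to DAS GFF; each feature's provenance state
#' is recorded as a NOTE token `WRITEBACK:STATE=<state>` so any renderer can
#' recover it. Tracks are distinguished by a `WRITEBACK:SOURCE=` NOTE.
#'
#' @param trackset A `wb_trackset` from [merge_tracks()].
#' @param segment A [wb_segment()] row describing the segment.
#' @return DAS GFF XML text.
#' @export
trackset_to_dasgff <- function(trackset, segment) {
  feats <- trackset
  feats$notes <- purrr::pmap(
    list(feats$notes, feats$state, feats$source),
    function(n, st, src) c(n, sprintf("WRITEBACK:STATE=%s", st),
                           sprintf("WRITEBACK:SOURCE=%s", src))
  )
  feats <- apply_protein_defaults(feats[, c("segment_id", feature_payload_cols())])
  # a feature id may legitimately repeat across tracks (disabled/extra modes)
  dup <- duplicated(paste(feats$segment_id, feats$feature_id))
  feats$feature_id[dup] <- paste0(feats$feature_id[dup], ":dup",
                                  cumsum(dup)[dup])
  write_dasgff(das_gff(segment, feats))
}
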