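# Input-quality rules applied on both sides of the wire: the client checks a
# feature before any network call, and the server re-checks it before any
# write, so the two verdicts always agree.

ISSUE_CODES <- c("START_AFTER_END", "OUT_OF_RANGE", "NONPOSITIVE_START",
                 "MISSING_ID", "BAD_ENUM")

issue <- function(code, field, message) {
  tibble(code = code, field = field, message = message)
}

no_issues <- function() issue("x", "x", "x")[0, ]

#' Validate a feature against a protein's length
#'
#' Applies the coordinate sanity rules for positional protein annotations:
#' the start amino acid must not come after the end, coordinates must stay
#' within `1..sequence_length`, the feature needs an id, and orientation and
#' phase (when set) must use their DAS tokens. Non-positional features
#' (`start = end = 0`) skip the range checks. A feature is acceptable
#' exactly when `1 <= start <= end <= sequence_length` or
#' `start = end = 0`.
#'
#' All applicable issues are reported, not just the first; issues are data,
#' not conditions.
#'
#' @param f A one-row feature tibble ([wb_feature()]), or a multi-row
#'   feature table (issues are then tagged by `feature_id`).
#' @param sequence_length Protein length in amino acids; `Inf` disables the
#'   upper bound (used server-side, where no reference sequence is known).
#' @return A tibble with columns `code`, `field`, `message` (plus
#'   `feature_id` for multi-row input); zero rows iff the feature is
#'   acceptable.
#' @examples
#' validate_feature(wb_feature("f1", start = 10, end = 5), 100)
#' @export
validate_feature <- function(f, sequence_length = Inf) {
  stopifnot(sequence_length >= 1)
  if (nrow(f) > 1) {
    out <- purrr::map2(seq_len(nrow(f)), f$feature_id, function(i, id) {
      mutate(validate_feature(f[i, ], sequence_length), feature_id = id)
    })
    return(bind_rows(c(list(mutate(no_issues(), feature_id = character())), out)))
  }
  issues <- no_issues()
  add <- function(code, field, message) {
    issues <<- bind_rows(issues, issue(code, field, message))
  }
  if (nrow(f) == 0) return(issues)
  if (is.na(f$feature_id) || !nzchar(f$feature_id)) {
    add("MISSING_ID", "feature_id", "feature id is missing")
  }
  s <- f$start; e <- f$end
  nonpositional <- !is.na(s) && !is.na(e) && s == 0 && e == 0
  if (!nonpositional) {
    if (is.na(s) || s < 1) {
      add("NONPOSITIVE_START", "start",
          sprintf("start %s is before the first amino acid", s))
    }
    if (!is.na(s) && !is.na(e) && s > e) {
      add("START_AFTER_END", "start",
          sprintf("start %d is after end %d", s, e))
    }
    if (!is.na(e) && (e < 1 || e > sequence_length)) {
      add("OUT_OF_RANGE", "end",
          sprintf("end %s is outside 1..%s", e, sequence_length))
    }
    if (!is.na(s) && s > sequence_length) {
      add("OUT_OF_RANGE", "start",
          sprintf("start %s is outside 1..%s", s, sequence_length))
    }
  }
  if (!is.na(f$orientation) && !f$orientation %in% ORIENTATIONS) {
    add("BAD_ENUM", "orientation",
        sprintf("orientation '%s' not one of +, -, 0", f$orientation))
  }
  if (!is.na(f$phase) && !f$phase %in% PHASES) {
    add("BAD_ENUM", "phase",
        sprintf("phase '%s' not one of 0, 1, 2, -", f$phase))
  }
  issues
}

#' Fill in protein defaults for orientation and phase
#'
#' Orientation and phase are genomic-specific DAS fields that do not apply
#' to protein annotations; unset values default to the "not applicable"
#' tokens (`"0"` for orientation, `"-"` for phase). Values already set are
#' left untouched, so the operation is idempotent.
#'
#' @param f A feature table (one or more rows).
#' @return The table with defaults applied.
#' @export
apply_protein_defaults <- function(f) {
  mutate(
    f,
    orientation = ifelse(is.na(.data$orientation), "0", .data$orientation),
    phase = ifelse(is.na(.data$phase), "-", .data$phase)
  )
}
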