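# Domain types: features, segments, DAS GFF documents.
#
# A feature is one positional protein annotation; coordinates are 1-based,
# fully closed amino-acid intervals. Non-positional features are encoded with
# start = end = 0 and skip range checks. A document is the DAS GFF wire
# object: segments, each carrying an ordered feature table.

ORIENTATIONS <- c("+", "-", "0")
PHASES <- c("0", "1", "2", "-")

#' Construct a feature record
#'
#' Builds a one-row tibble describing a single positional protein annotation
#' in DAS terms: a TYPE (with optional controlled-vocabulary id), a METHOD,
#' 1-based inclusive start/end amino-acid coordinates, an optional score, and
#' free-text notes and links. Feature tables are just row-bound results of
#' this constructor, so they pipe straight into dplyr.
#'
#' Orientation and phase are genomic concepts that do not apply to proteins;
#' they default to unset (`NA`) and [apply_protein_defaults()] fills in the
#' DAS "not applicable" tokens (`"0"` and `"-"`).
#'
#' @param feature_id Feature identifier, unique within its segment.
#' @param label Human-readable label; defaults to the id.
#' @param type_id,type_cvid,type_category Annotation type, its ontology term
#'   id (e.g. `"SO:0000417"`) and DAS category.
#' @param method_id,method_cvid Annotation method and its evidence-code
#'   ontology term id (e.g. `"ECO:0000269"`).
#' @param start,end 1-based inclusive coordinates; both 0 for a
#'   non-positional feature.
#' @param score Numeric score, or `NA` for not applicable (serialized `"-"`).
#' @param orientation One of `"+"`, `"-"`, `"0"`, or `NA` for unset.
#' @param phase One of `"0"`, `"1"`, `"2"`, `"-"`, or `NA` for unset.
#' @param notes Character vector of free-text notes (ordered).
#' @param links Data frame with columns `href` and `label`, or `NULL`.
#' @return A one-row tibble with the canonical feature columns.
#' @examples
#' wb_feature("f1", type_id = "polypeptide_domain",
#'            type_cvid = "SO:0000417", start = 10, end = 42)
#' @export
wb_feature <- function(feature_id,
                       label = feature_id,
                       type_id = "",
                       type_cvid = "",
                       type_category = "",
                       method_id = "",
                       method_cvid = "",
                       start = 0L,
                       end = 0L,
                       score = NA_real_,
                       orientation = NA_character_,
                       phase = NA_character_,
                       notes = character(),
                       links = NULL) {
  if (is.null(links)) links <- empty_links()
  links <- as_tibble(links)
  stopifnot(identical(names(links), c("href", "label")))
  tibble(
    feature_id = as.character(feature_id),
    label = as.character(label),
    type_id = as.character(type_id),
    type_cvid = as.character(type_cvid),
    type_category = as.character(type_category),
    method_id = as.character(method_id),
    method_cvid = as.character(method_cvid),
    start = as.integer(start),
    end = as.integer(end),
    score = as.double(score),
    orientation = as.character(orientation),
    phase = as.character(phase),
    notes = list(as.character(notes)),
    links = list(links)
  )
}

empty_links <- function() tibble(href = character(), label = character())

#' An empty feature table with the canonical columns
#' @return A zero-row tibble with the columns produced by [wb_feature()].
#' @export
wb_feature_table <- function() wb_feature("x")[0, ]

feature_payload_cols <- function() names(wb_feature_table())

#' Construct a segment record
#'
#' A segment is the DAS addressing unit: here a protein identified by its
#' accession. Coordinates are 1-based; `sequence_length` is the full protein
#' length and equals `stop` when the whole sequence is covered.
#'
#' @param segment_id Sequence accession (e.g. a UniProt accession).
#' @param start,stop Covered range, `1 <= start <= stop`.
#' @param version_label Free-text sequence version label.
#' @param sequence_length Full sequence length; defaults to `stop`.
#' @return A one-row tibble.
#' @export
wb_segment <- function(segment_id, start = 1L, stop = 1L,
                       version_label = "", sequence_length = stop) {
  tibble(
    segment_id = as.character(segment_id),
    start = as.integer(start),
    stop = as.integer(stop),
    version_label = as.character(version_label),
    sequence_length = as.integer(sequence_length)
  )
}

#' Construct a DAS GFF document
#'
#' Bundles a segment table and a feature table (joined by `segment_id`) into
#' the in-memory form of a DAS GFF feature document, the sole wire format of
#' the writeback protocol. Invariants are checked eagerly: unique segment
#' ids, features referencing known segments, and per-feature structural
#' rules (non-empty id, `1 <= start <= end` for positional features,
#' `start = end = 0` for non-positional ones, orientation/phase drawn from
#' their token sets when set).
#'
#' @param segments Tibble from [wb_segment()] rows.
#' @param features Tibble from [wb_feature()] rows, with a `segment_id`
#'   column (added automatically when there is exactly one segment).
#' @param source_href Originating URL, recorded on the GFF element.
#' @param check Verify the invariants (default)? `check = FALSE` admits a
#'   structurally broken document so that [validate_feature()] can report
#'   its problems as data.
#' @return An object of class `das_gff`.
#' @examples
#' doc <- das_gff(wb_segment("P12345", 1, 100),
#'                wb_feature("f1", start = 10, end = 20))
#' @export
das_gff <- function(segments = wb_segment("unknown")[0, ],
                    features = wb_feature_table(),
                    source_href = "",
                    check = TRUE) {
  segments <- as_tibble(segments)
  features <- as_tibble(features)
  if (!"segment_id" %in% names(features)) {
    if (nrow(features) > 0 && nrow(segments) != 1) {
      stop_input("features need a segment_id column when the document has != 1 segment")
    }
    features$segment_id <- rep(segments$segment_id[1], nrow(features))
  }
  features <- features[, c("segment_id", feature_payload_cols())]
  doc <- structure(
    list(source_href = source_href, segments = segments, features = features),
    class = "das_gff"
  )
  if (check) assert_document(doc)
  doc
}

#' @export
print.das_gff <- function(x, ...) {
  cat(sprintf("<das_gff> %d segment(s), %d feature(s)\n",
              nrow(x$segments), nrow(x$features)))
  if (nzchar(x$source_href)) cat("  href:", x$source_href, "\n")
  print(x$features[, c("segment_id", "feature_id", "type_id", "start", "end")])
  invisible(x)
}

# Structural (length-independent) invariants; full coordinate validation
# against a protein length lives in validate_feature().
assert_document <- function(doc) {
  segs <- doc$segments
  if (anyDuplicated(segs$segment_id)) {
    stop_validation("duplicate segment ids in document")
  }
  if (any(!nzchar(segs$segment_id))) stop_validation("empty segment id")
  if (any(segs$start > segs$stop) || any(segs$stop > segs$sequence_length) ||
      any(segs$start < 1)) {
    stop_validation("segment coordinates violate start <= stop <= sequence_length")
  }
  feats <- doc$features
  if (nrow(feats) == 0) return(invisible(doc))
  if (!all(feats$segment_id %in% segs$segment_id)) {
    stop_validation("feature references unknown segment")
  }
  dup <- duplicated(feats[, c("segment_id", "feature_id")])
  if (any(dup)) stop_validation("duplicate feature id within a segment")
  bad <- purrr::pmap_lgl(
    feats[, c("feature_id", "start", "end", "orientation", "phase")],
    function(feature_id, start, end, orientation, phase) {
      !nzchar(feature_id) ||
        !((start == 0 && end == 0) || (start >= 1 && start <= end)) ||
        (!is.na(orientation) && !orientation %in% ORIENTATIONS) ||
        (!is.na(phase) && !phase %in% PHASES)
    }
  )
  if (any(bad)) {
    stop_validation(
      sprintf("feature invariant violated for: %s",
              paste(feats$feature_id[bad], collapse = ", "))
    )
  }
  invisible(doc)
}

# field-by-field equality of two feature tables (order-sensitive)
features_equal <- function(a, b) {
  if (nrow(a) != nrow(b)) return(FALSE)
  cols <- intersect(names(a), names(b))
  for (col in cols) {
    va <- a[[col]]; vb <- b[[col]]
    if (is.list(va)) {
      same <- purrr::map2_lgl(va, vb, function(x, y) isTRUE(all.equal(x, y, check.attributes = FALSE)))
      if (!all(same)) return(FALSE)
    } else {
      if (!isTRUE(all.equal(va, vb, check.attributes = FALSE))) return(FALSE)
    }
  }
  TRUE
}

docs_equal <- function(a, b) {
  isTRUE(all.equal(a$segments, b$segments, check.attributes = FALSE)) &&
    features_equal(a$features, b$features) &&
    identical(a$source_href, b$source_href)
}
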