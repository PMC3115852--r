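# DAS GFF XML reader/writer.
#
# Canonical dialect (DAS 1.6 feature response):
#   <DASGFF><GFF version="1.6" href="...">
#     <SEGMENT id start stop version [sequence_length]>
#       <FEATURE id label>
#         <TYPE id cvId category/><METHOD id cvId/>
#         <START/><END/><SCORE/><ORIENTATION/><PHASE/>
#         <NOTE/>* <LINK href>label</LINK>*
#       </FEATURE>* </SEGMENT>* </GFF></DASGFF>
#
# sequence_length is emitted only when it differs from stop (foreign DAS
# clients ignore unknown attributes; our parser defaults it to stop), so
# documents round-trip exactly. Score "not applicable" is the literal "-".
# Encoding is fixed to UTF-8 and the XML declaration is always emitted.

#' Parse a DAS GFF XML feature document
#'
#' Reads the XML wire format used in both directions by the writeback
#' protocol into a [das_gff()] object. Unknown child elements of FEATURE are
#' ignored with a single classed warning; sibling order of FEATURE children
#' does not matter.
#'
#' @param x XML text, or a path to an XML file.
#' @param check Enforce document invariants (default)? See [das_gff()].
#' @return A [das_gff()] object.
#' @section Errors:
#' Malformed XML signals a `daswb_structural_error`; a missing mandatory
#' attribute (SEGMENT id, FEATURE id) signals a `daswb_schema_error` whose
#' `path` field identifies the offending element.
#' @export
read_dasgff <- function(x, check = TRUE) {
  txt <- x
  if (length(x) == 1 && !grepl("<", x, fixed = TRUE) && file.exists(x)) {
    txt <- paste(readLines(x, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  }
  xml <- tryCatch(
    xml2::read_xml(txt, options = c()),
    error = function(e) stop_structural(paste0("malformed XML: ", conditionMessage(e)))
  )
  if (xml2::xml_name(xml) != "DASGFF") {
    stop_schema("root element is not DASGFF", path = "/")
  }
  gff <- xml2::xml_find_first(xml, "./GFF")
  if (inherits(gff, "xml_missing")) stop_schema("missing GFF element", path = "/DASGFF")
  source_href <- xml2::xml_attr(gff, "href", default = "")

  unknown <- character()
  known_children <- c("TYPE", "METHOD", "START", "END", "SCORE",
                      "ORIENTATION", "PHASE", "NOTE", "LINK")

  seg_nodes <- xml2::xml_find_all(gff, "./SEGMENT")
  segments <- wb_segment("x")[0, ]
  features <- wb_feature_table()
  features$segment_id <- character()

  for (sn in seg_nodes) {
    sid <- xml2::xml_attr(sn, "id")
    if (is.na(sid) || !nzchar(sid)) {
      stop_schema("SEGMENT without id attribute", path = "/DASGFF/GFF/SEGMENT")
    }
    sstart <- as.integer(xml2::xml_attr(sn, "start", default = "1"))
    sstop <- as.integer(xml2::xml_attr(sn, "stop", default = "1"))
    slen <- xml2::xml_attr(sn, "sequence_length")
    slen <- if (is.na(slen)) sstop else as.integer(slen)
    segments <- bind_rows(segments, wb_segment(
      sid, sstart, sstop,
      version_label = xml2::xml_attr(sn, "version", default = ""),
      sequence_length = slen
    ))
    for (fn in xml2::xml_find_all(sn, "./FEATURE")) {
      fid <- xml2::xml_attr(fn, "id")
      if (is.na(fid) || !nzchar(fid)) {
        stop_schema("FEATURE without id attribute",
                    path = sprintf("/DASGFF/GFF/SEGMENT[@id='%s']/FEATURE", sid))
      }
      kids <- xml2::xml_children(fn)
      nm <- xml2::xml_name(kids)
      unknown <- c(unknown, setdiff(nm, known_children))

      first_text <- function(el) {
        i <- which(nm == el)
        if (length(i) == 0) NA_character_ else xml2::xml_text(kids[[i[1]]])
      }
      first_attr <- function(el, at) {
        i <- which(nm == el)
        if (length(i) == 0) NA_character_ else xml2::xml_attr(kids[[i[1]]], at)
      }
      chr0 <- function(v) if (is.na(v)) "" else v
      score_txt <- first_text("SCORE")
      link_idx <- which(nm == "LINK")
      links <- tibble(
        href = map_chr(link_idx, function(i) chr0(xml2::xml_attr(kids[[i]], "href"))),
        label = map_chr(link_idx, function(i) xml2::xml_text(kids[[i]]))
      )
      f <- wb_feature(
        feature_id = fid,
        label = chr0(xml2::xml_attr(fn, "label")),
        type_id = chr0(first_attr("TYPE", "id")),
        type_cvid = chr0(first_attr("TYPE", "cvId")),
        type_category = chr0(first_attr("TYPE", "category")),
        method_id = chr0(first_attr("METHOD", "id")),
        method_cvid = chr0(first_attr("METHOD", "cvId")),
        start = as.integer(chr0(first_text("START")) %0% "0"),
        end = as.integer(chr0(first_text("END")) %0% "0"),
        score = if (is.na(score_txt) || score_txt == "-") NA_real_ else as.double(score_txt),
        orientation = first_text("ORIENTATION"),
        phase = first_text("PHASE"),
        notes = xml2::xml_text(kids[nm == "NOTE"]),
        links = links
      )
      f$segment_id <- sid
      features <- bind_rows(features, f)
    }
  }
  if (length(unknown) > 0) {
    warn(sprintf("ignored unknown feature child element(s): %s",
                 paste(sort(unique(unknown)), collapse = ", ")),
         class = "daswb_unknown_elements")
  }
  das_gff(segments, features, source_href = source_href, check = check)
}

`%0%` <- function(a, b) if (!nzchar(a)) b else a

#' Serialize a DAS GFF document to XML text
#'
#' Emits a DAS 1.6 GFF XML document as a single UTF-8 string with the XML
#' declaration. Output is deterministic: element and attribute order are
#' fixed, so serializing the same document twice yields byte-identical text.
#'
#' Unset (`NA`) orientation and phase are emitted as the protein
#' "not applicable" tokens (`0` and `-`), exactly as
#' [apply_protein_defaults()] would set them; all set values are emitted
#' verbatim.
#'
#' @param doc A [das_gff()] object satisfying all invariants.
#' @param file Optional path; when given the text is also written there.
#' @return The XML text, invisibly when `file` is given.
#' @export
write_dasgff <- function(doc, file = NULL) {
  assert_document(doc)
  doc$features <- apply_protein_defaults(doc$features)
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    s <- gsub(">", "&gt;", s, fixed = TRUE)
    gsub("\"", "&quot;", s, fixed = TRUE)
  }
  num <- function(x) {
    if (is.na(x)) "-" else as.character(x)
  }
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<DASGFF><GFF version=\"1.6\" href=\"%s\">", esc(doc$source_href))
  )
  for (i in seq_len(nrow(doc$segments))) {
    s <- doc$segments[i, ]
    seg_attrs <- sprintf("id=\"%s\" start=\"%d\" stop=\"%d\" version=\"%s\"",
                         esc(s$segment_id), s$start, s$stop, esc(s$version_label))
    if (s$sequence_length != s$stop) {
      seg_attrs <- paste0(seg_attrs,
                          sprintf(" sequence_length=\"%d\"", s$sequence_length))
    }
    out <- c(out, sprintf("<SEGMENT %s>", seg_attrs))
    feats <- doc$features[doc$features$segment_id == s$segment_id, ]
    for (j in seq_len(nrow(feats))) {
      f <- feats[j, ]
      out <- c(
        out,
        sprintf("<FEATURE id=\"%s\" label=\"%s\">", esc(f$feature_id), esc(f$label)),
        sprintf("<TYPE id=\"%s\" cvId=\"%s\" category=\"%s\">%s</TYPE>",
                esc(f$type_id), esc(f$type_cvid), esc(f$type_category), esc(f$type_id)),
        sprintf("<METHOD id=\"%s\" cvId=\"%s\">%s</METHOD>",
                esc(f$method_id), esc(f$method_cvid), esc(f$method_id)),
        sprintf("<START>%d</START>", f$start),
        sprintf("<END>%d</END>", f$end),
        sprintf("<SCORE>%s</SCORE>", num(f$score)),
        sprintf("<ORIENTATION>%s</ORIENTATION>", f$orientation),
        sprintf("<PHASE>%s</PHASE>", f$phase)
      )
      for (note in f$notes[[1]]) {
        out <- c(out, sprintf("<NOTE>%s</NOTE>", esc(note)))
      }
      lk <- f$links[[1]]
      for (k in seq_len(nrow(lk))) {
        out <- c(out, sprintf("<LINK href=\"%s\">%s</LINK>",
                              esc(lk$href[k]), esc(lk$label[k])))
      }
      out <- c(out, "</FEATURE>")
    }
    out <- c(out, "</SEGMENT>")
  }
  out <- c(out, "</GFF></DASGFF>")
  txt <- paste(out, collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}
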