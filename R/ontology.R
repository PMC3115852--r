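# Ontology-assisted term entry. DAS 1.6 recommends controlled vocabularies
# for feature types (Sequence Ontology, Protein Modification ontology,
# BioSapiens annotation ontology) and for methods (Evidence Code Ontology).
# Small term subsets ship with the package as two-column TSV files so the
# type-ahead aid works offline; they are illustrative subsets, not the full
# ontologies (the BS list is synthetic — see the file header).

ONTOLOGY_IDS <- c("SO", "MOD", "BS", "ECO")

#' Read one bundled or external ontology term list
#'
#' Term lists are two-column tab-separated files (`term_id`, `term_name`),
#' one file per ontology. Lines starting with `#` are comments.
#'
#' @param path Path to a TSV file.
#' @param ontology_id One of `"SO"`, `"MOD"`, `"BS"`, `"ECO"`.
#' @return A tibble with columns `ontology_id`, `term_id`, `term_name`.
#' @export
read_term_list <- function(path, ontology_id) {
  ontology_id <- match.arg(ontology_id, ONTOLOGY_IDS)
  raw <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           col.names = c("term_id", "term_name"),
                           colClasses = "character")
  out <- as_tibble(raw)
  if (anyDuplicated(out$term_id)) {
    stop_input(sprintf("duplicate term ids in %s", path))
  }
  mutate(out, ontology_id = ontology_id, .before = 1)
}

#' Load the bundled ontology term subsets
#'
#' @return A tibble with one row per term across SO, MOD, BS and ECO.
#' @export
load_bundled_ontologies <- function() {
  files <- c(SO = "so_terms.tsv", MOD = "mod_terms.tsv",
             BS = "bs_terms.tsv", ECO = "eco_terms.tsv")
  bind_rows(imap(files, function(f, id) {
    read_term_list(system.file("extdata", f, package = "daswriteback",
                               mustWork = TRUE), id)
  }))
}

#' Suggest ontology terms for the type or method field
#'
#' Reproduces the type-ahead aid of the annotation form: while the user
#' types in the "type" or "method" field, matching controlled-vocabulary
#' terms are suggested. The `type` field searches the SO, MOD and BS lists;
#' the `method` field searches ECO only. Matching is a case-insensitive
#' prefix match on either the term name or the term id; results are ranked
#' by term name (ties by id) and capped.
#'
#' @param field `"type"` or `"method"`.
#' @param prefix Prefix typed so far; an empty prefix returns the first
#'   `limit` terms by name.
#' @param terms Term tibble as from [load_bundled_ontologies()].
#' @param limit Maximum number of suggestions.
#' @return A tibble with columns `ontology_id`, `term_id`, `term_name`.
#' @export
suggest_terms <- function(field, prefix = "", terms = load_bundled_ontologies(),
                          limit = 10L) {
  if (!field %in% c("type", "method")) {
    stop_input(sprintf("unknown field '%s': must be 'type' or 'method'", field))
  }
  pool <- if (field == "type") {
    filter(terms, .data$ontology_id %in% c("SO", "MOD", "BS"))
  } else {
    filter(terms, .data$ontology_id == "ECO")
  }
  p <- tolower(prefix)
  hits <- filter(pool, startsWith(tolower(.data$term_name), p) |
                   startsWith(tolower(.data$term_id), p))
  hits <- arrange(hits, .data$term_name, .data$term_id)
  head(hits, limit)
}
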