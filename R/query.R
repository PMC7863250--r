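# Hierarchy-aware retrieval. A query with a broader term finds everything
# annotated with any of its narrower terms, so all retrieval goes through
# the reflexive-transitive closure of the is_a child relation.

assert_term <- function(th, term_id) {
  term_id <- normalize_eid(term_id)
  if (!term_id %in% th$terms$term_id) {
    rlang::abort(paste0("unknown term: ", term_id))
  }
  term_id
}

#' Strict descendants of a term
#'
#' All terms below `term_id` via the transitive closure of is_a, in sorted
#' id order.
#'
#' @param th a `gmo_thesaurus`.
#' @param term_id an element id.
#' @return Character vector of term ids (empty for a leaf).
#' @export
#' @examples
#' th <- build_example_thesaurus()
#' descendants(th, "e:0000188")
descendants <- function(th, term_id) {
  term_id <- assert_term(th, term_id)
  out <- character()
  frontier <- th$children[[term_id]]
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- unlist(th$children[frontier], use.names = FALSE)
  }
  sort(out)
}

#' A term together with its descendants
#'
#' The reflexive-transitive is_a closure: the query-expansion set that
#' makes a broader-term search find everything annotated at narrower
#' levels.
#'
#' @inheritParams descendants
#' @return Sorted character vector of term ids, always containing
#'   `term_id` itself.
#' @export
expand_term <- function(th, term_id) {
  term_id <- assert_term(th, term_id)
  sort(c(term_id, descendants(th, term_id)))
}

# strict ancestors, nearest first
ancestors <- function(th, term_id) {
  term_id <- assert_term(th, term_id)
  parent_of <- stats::setNames(th$terms$parent_id, th$terms$term_id)
  out <- character()
  cur <- parent_of[[term_id]]
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- parent_of[[cur]]
  }
  out
}

#' Search terms by preferred name or synonym
#'
#' Case-insensitive exact match (no substring matching; exactness is what
#' makes automated cross-database joins safe).
#'
#' @param th a `gmo_thesaurus`.
#' @param text query string.
#' @param fields which fields to match: any subset of `"name"`,
#'   `"synonym"`.
#' @return A tibble with columns `term_id`, `name`, `matched_field`,
#'   sorted by term id; zero rows when nothing matches.
#' @export
#' @examples
#' th <- build_example_thesaurus()
#' find_terms(th, "pNOS")
find_terms <- function(th, text, fields = c("name", "synonym")) {
  fields <- match.arg(fields, several.ok = TRUE)
  t <- th$terms
  hits <- list()
  q <- tolower(text)
  if ("name" %in% fields) {
    i <- which(tolower(t$name) == q)
    if (length(i)) {
      hits <- c(hits, list(tibble::tibble(
        term_id = t$term_id[i], name = t$name[i], matched_field = "name"
      )))
    }
  }
  if ("synonym" %in% fields) {
    i <- which(purrr::map_lgl(t$synonyms, function(s) q %in% tolower(s)))
    if (length(i)) {
      hits <- c(hits, list(tibble::tibble(
        term_id = t$term_id[i], name = t$name[i], matched_field = "synonym"
      )))
    }
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      term_id = character(), name = character(), matched_field = character()
    ))
  }
  dplyr::arrange(dplyr::distinct(out), .data$term_id)
}

#' Resolve a cross-database identifier to thesaurus terms
#'
#' Exact lookup in the cross-reference annotations. Namespaces: `"BCH"`
#' (integer Biosafety Clearing-House element id; not assumed unique, all
#' carriers are returned sorted), `"Trait"` (trait id `t:NNNNNNN`, printed
#' escaped-colon form accepted) and `"Donor"` (donor organism annotation,
#' spaces or underscores).
#'
#' @param th a `gmo_thesaurus`.
#' @param namespace one of `"BCH"`, `"Trait"`, `"Donor"`.
#' @param value the identifier to resolve.
#' @return Sorted character vector of term ids; empty when unmapped.
#' @export
#' @examples
#' th <- build_example_thesaurus()
#' resolve_xref(th, "BCH", 14972)
resolve_xref <- function(th, namespace, value) {
  t <- th$terms
  ids <- switch(
    namespace,
    BCH = t$term_id[!is.na(t$bch_id) & t$bch_id == as.integer(value)],
    Trait = {
      v <- normalize_trait_id(as.character(value))
      t$term_id[purrr::map_lgl(t$trait_refs, function(x) v %in% x)]
    },
    Donor = {
      v <- gsub("_", " ", as.character(value))
      t$term_id[!is.na(t$donor) & t$donor == v]
    },
    rlang::abort(paste0("unknown xref namespace: ", namespace))
  )
  sort(ids)
}
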