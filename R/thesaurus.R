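# The thesaurus is a mono-hierarchy: every term except the root has exactly
# one broader term via is_a, so the whole vocabulary is a single tree of at
# most five levels (0 = root "genetic element", 1 = element type, 2 =
# functional long name, 3 = concrete element designation, 4 = sequence
# variant).

#' @importFrom rlang .data
NULL

ID_RE <- "^e:[0-9]{7}$"

format_eid <- function(n) sprintf("e:%07d", as.integer(n))

# accept the printed form "e: 0000415" (space after the colon) on input
normalize_eid <- function(id) {
  sub("^e:[[:space:]]+", "e:", trimws(id))
}

eid_number <- function(id) as.integer(sub("^e:", "", id))

modification_from_name <- function(name) {
  dplyr::case_when(
    grepl("_genome_edited(-|$)", name) ~ "genome_edited",
    grepl("_siRNAas(-|$)", name) ~ "siRNA_antisense",
    grepl("_siRNAs(-|$)", name) ~ "siRNA_sense",
    grepl("_siRNAu(-|$)", name) ~ "siRNA_undefined",
    TRUE ~ NA_character_
  )
}

empty_terms <- function() {
  tibble::tibble(
    term_id = character(),
    name = character(),
    level = integer(),
    parent_id = character(),
    definition = character(),
    def_refs = list(),
    comment = character(),
    synonyms = list(),
    trait_refs = list(),
    trait_labels = list(),
    bch_id = integer(),
    donor = character(),
    modification = character(),
    other_xrefs = list(),
    extra_tags = list()
  )
}

default_metadata <- function() {
  c("format-version" = "1.2")
}

build_children <- function(terms) {
  ids <- unique(terms$term_id)
  kids <- split(terms$term_id, factor(terms$parent_id, levels = ids))
  lapply(kids, function(x) sort(x))
}

# Levels by breadth-first walk from the parentless term(s). Terms not
# reachable from a root (orphans, cycles) get NA and are reported by
# validate_thesaurus() rather than raising here.
compute_levels <- function(terms) {
  lev <- stats::setNames(rep(NA_integer_, nrow(terms)), terms$term_id)
  frontier <- terms$term_id[is.na(terms$parent_id)]
  lev[frontier] <- 0L
  children <- build_children(terms)
  while (length(frontier)) {
    nxt <- unlist(children[intersect(frontier, names(children))],
                  use.names = FALSE)
    nxt <- nxt[is.na(lev[nxt])]
    if (!length(nxt)) break
    lev[nxt] <- lev[terms$parent_id[match(nxt, terms$term_id)]] + 1L
    frontier <- nxt
  }
  unname(lev[terms$term_id])
}

#' Create a genetic-element thesaurus
#'
#' Builds a `gmo_thesaurus` object from a term table (or an empty one).
#' Terms are kept sorted by term id; levels are recomputed from the
#' `parent_id` links and a child index is maintained. No structural
#' validation is performed here — use [validate_thesaurus()] to obtain the
#' full list of violations.
#'
#' @param terms a tibble with (a subset of) the columns of the term table;
#'   missing columns are filled with empty defaults. `NULL` gives an empty
#'   thesaurus.
#' @param metadata named character vector of OBO header key-value pairs.
#' @return A `gmo_thesaurus` object: a list with elements `terms` (tibble),
#'   `metadata` (named character) and `children` (named list index).
#' @export
#' @examples
#' th <- gmo_thesaurus()
#' th <- add_term(th, "genetic element", term_id = "e:0000000")
gmo_thesaurus <- function(terms = NULL, metadata = default_metadata()) {
  tmpl <- empty_terms()
  if (is.null(terms)) {
    terms <- tmpl
  } else {
    terms <- tibble::as_tibble(terms)
    for (col in setdiff(names(tmpl), names(terms))) {
      proto <- tmpl[[col]]
      terms[[col]] <- if (is.list(proto)) {
        rep(list(character(0)), nrow(terms))
      } else {
        rep(proto[NA_integer_], nrow(terms))
      }
    }
    terms <- terms[names(tmpl)]
    terms$term_id <- normalize_eid(terms$term_id)
    terms$parent_id <- ifelse(
      is.na(terms$parent_id), NA_character_, normalize_eid(terms$parent_id)
    )
  }
  terms <- dplyr::arrange(terms, .data$term_id)
  terms$level <- compute_levels(terms)
  terms$modification <- modification_from_name(terms$name)
  structure(
    list(terms = terms, metadata = metadata,
         children = build_children(terms), extra_stanzas = character()),
    class = "gmo_thesaurus"
  )
}

#' @export
print.gmo_thesaurus <- function(x, ...) {
  n <- nrow(x$terms)
  cat("<gmo_thesaurus> ", n, " term", if (n != 1) "s", "\n", sep = "")
  if (n) {
    tab <- table(factor(x$terms$level, levels = 0:4), useNA = "ifany")
    cat("  terms per level: ",
        paste(names(tab), unname(tab), sep = ":", collapse = "  "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Term table of a thesaurus
#'
#' @param x a `gmo_thesaurus`.
#' @param ... unused.
#' @return The term tibble (one row per term).
#' @export
tidy.gmo_thesaurus <- function(x, ...) {
  x$terms
}

#' One-row summary of a thesaurus
#'
#' @param x a `gmo_thesaurus`.
#' @param ... unused.
#' @return A one-row tibble with term counts per level and annotation
#'   totals.
#' @export
glance.gmo_thesaurus <- function(x, ...) {
  t <- x$terms
  tibble::tibble(
    n_terms = nrow(t),
    n_level1 = sum(t$level == 1L, na.rm = TRUE),
    n_level2 = sum(t$level == 2L, na.rm = TRUE),
    n_level3 = sum(t$level == 3L, na.rm = TRUE),
    n_level4 = sum(t$level == 4L, na.rm = TRUE),
    n_synonyms = sum(lengths(t$synonyms)),
    n_bch_xrefs = sum(!is.na(t$bch_id)),
    n_trait_xrefs = sum(lengths(t$trait_refs))
  )
}

term_row <- function(th, term_id) {
  i <- match(term_id, th$terms$term_id)
  if (is.na(i)) {
    rlang::abort(paste0("unknown term: ", term_id))
  }
  th$terms[i, ]
}

#' Insert a term into a thesaurus
#'
#' The term's level is computed as its parent's level plus one (0 for the
#' root). Insertions that would break the mono-hierarchy are rejected:
#' duplicate ids, unknown parents, self-parentage, a second root, a level
#' below the maximum depth of 4, and duplicate preferred names.
#'
#' @param th a `gmo_thesaurus`.
#' @param name preferred designation of the term.
#' @param parent_id id of the broader term; `NA` only for the root.
#' @param term_id id in the element namespace (`e:` + 7 digits); defaults
#'   to the smallest unused id. The printed form with a space after the
#'   colon is accepted and normalized.
#' @param definition,def_refs definition text and its citation strings.
#' @param comment free-text function note (citations included in the text).
#' @param synonyms character vector of non-preferred names.
#' @param trait_refs,trait_labels trait identifiers (`t:` + 7 digits) and
#'   optional parallel labels.
#' @param bch_id optional positive integer Biosafety Clearing-House id.
#' @param donor optional donor-organism annotation (the source organism
#'   recorded as a Donor cross-reference).
#' @param other_xrefs character vector of further `NAMESPACE:value`
#'   cross-references, preserved verbatim.
#' @param extra_tags character vector of raw OBO tag lines preserved
#'   verbatim on round-trips.
#' @return The updated `gmo_thesaurus`.
#' @export
#' @examples
#' th <- gmo_thesaurus()
#' th <- add_term(th, "genetic element", term_id = "e:0000000")
#' th <- add_term(th, "promoter", parent_id = "e:0000000")
add_term <- function(th, name, parent_id = NA_character_, term_id = NULL,
                     definition = NA_character_, def_refs = character(),
                     comment = NA_character_, synonyms = character(),
                     trait_refs = character(), trait_labels = NULL,
                     bch_id = NA_integer_, donor = NA_character_,
                     other_xrefs = character(), extra_tags = character()) {
  stopifnot(inherits(th, "gmo_thesaurus"), is.character(name), nzchar(name))
  if (is.null(term_id)) {
    term_id <- next_free_id(th)
  }
  term_id <- normalize_eid(term_id)
  if (!grepl(ID_RE, term_id)) {
    rlang::abort(paste0("term id does not match e:NNNNNNN: ", term_id))
  }
  if (term_id %in% th$terms$term_id) {
    rlang::abort(paste0("duplicate term id: ", term_id))
  }
  if (name %in% th$terms$name) {
    rlang::abort(paste0("duplicate preferred name: ", name))
  }
  if (is.na(parent_id)) {
    if (any(is.na(th$terms$parent_id))) {
      rlang::abort("thesaurus already has a root; new term needs a parent")
    }
    level <- 0L
  } else {
    parent_id <- normalize_eid(parent_id)
    if (identical(parent_id, term_id)) {
      rlang::abort("a term cannot be its own parent (cycle)")
    }
    parent <- th$terms[match(parent_id, th$terms$term_id), ]
    if (nrow(parent) == 0L || is.na(parent$term_id)) {
      rlang::abort(paste0("unknown parent: ", parent_id))
    }
    level <- parent$level + 1L
    if (is.na(level) || level > 4L) {
      rlang::abort(paste0(
        "level ", level, " inconsistent with the five-level hierarchy"
      ))
    }
  }
  if (is.null(trait_labels)) {
    trait_labels <- rep(NA_character_, length(trait_refs))
  }
  stopifnot(length(trait_labels) == length(trait_refs))
  row <- tibble::tibble(
    term_id = term_id, name = name, level = level, parent_id = parent_id,
    definition = definition, def_refs = list(as.character(def_refs)),
    comment = comment, synonyms = list(as.character(synonyms)),
    trait_refs = list(as.character(trait_refs)),
    trait_labels = list(as.character(trait_labels)),
    bch_id = as.integer(bch_id), donor = donor,
    modification = modification_from_name(name),
    other_xrefs = list(as.character(other_xrefs)),
    extra_tags = list(as.character(extra_tags))
  )
  terms <- dplyr::arrange(dplyr::bind_rows(th$terms, row), .data$term_id)
  th$terms <- terms
  th$children <- build_children(terms)
  th
}

#' Smallest unused element identifier
#'
#' Scans the `e:` namespace and returns the smallest unused 7-digit id
#' starting from `e:0000001` (`e:0000000` is conventionally the root).
#' Deterministic: gaps are filled first.
#'
#' @param th a `gmo_thesaurus`.
#' @return An id string.
#' @export
next_free_id <- function(th) {
  used <- eid_number(grep(ID_RE, th$terms$term_id, value = TRUE))
  n <- 1L
  used <- sort(used[used >= 1L])
  for (u in used) {
    if (u > n) break
    n <- u + 1L
  }
  if (n > 9999999L) {
    rlang::abort("element id space exhausted")
  }
  format_eid(n)
}

# level-1 ancestor's name for every term (NA where the walk fails)
level1_ancestor <- function(th) {
  t <- th$terms
  lev <- t$level
  parent_of <- stats::setNames(t$parent_id, t$term_id)
  out <- rep(NA_character_, nrow(t))
  for (i in seq_len(nrow(t))) {
    cur <- t$term_id[i]
    steps <- 0L
    while (!is.na(cur) && steps <= nrow(t)) {
      l <- lev[match(cur, t$term_id)]
      if (!is.na(l) && l == 1L) {
        out[i] <- t$name[match(cur, t$term_id)]
        break
      }
      cur <- if (cur %in% names(parent_of)) parent_of[[cur]] else NA_character_
      steps <- steps + 1L
    }
  }
  out
}

#' Validate the structure of a thesaurus
#'
#' Performs an exhaustive structural audit and returns the violations as
#' data (never as conditions): id-pattern breaks, duplicate ids or
#' preferred names, missing/multiple roots, orphans and cycles, level gaps
#' beyond the five-level hierarchy, level_1 names outside the controlled
#' type list, prefixes inconsistent with the level_1 ancestor, invalid
#' level_3/level_4 name grammar and unknown donor codes. An empty result
#' means the thesaurus conforms.
#'
#' @param th a `gmo_thesaurus`.
#' @param donors,prefixes registries used for grammar checks.
#' @return A tibble with columns `rule`, `term_id`, `message`, ordered by
#'   rule then term id.
#' @export
validate_thesaurus <- function(th, donors = default_donor_registry(),
                               prefixes = default_prefix_registry()) {
  t <- th$terms
  v <- list()
  viol <- function(rule, term_id, message) {
    tibble::tibble(rule = rule, term_id = term_id, message = message)
  }
  bad_id <- t$term_id[!grepl(ID_RE, t$term_id)]
  for (id in bad_id) {
    v <- c(v, list(viol("id_pattern", id, "id does not match e:NNNNNNN")))
  }
  dup <- unique(t$term_id[duplicated(t$term_id)])
  for (id in dup) {
    v <- c(v, list(viol("duplicate_id", id, "term id occurs more than once")))
  }
  dup_nm <- unique(t$name[duplicated(t$name)])
  for (nm in dup_nm) {
    ids <- t$term_id[t$name == nm]
    v <- c(v, list(viol(
      "duplicate_name", ids[2],
      paste0("preferred name \"", nm, "\" is ambiguous")
    )))
  }
  n_root <- sum(is.na(t$parent_id))
  if (nrow(t) > 0L && n_root != 1L) {
    v <- c(v, list(viol(
      "root", NA_character_,
      paste0("expected exactly one root, found ", n_root)
    )))
  }
  missing_parent <- !is.na(t$parent_id) & !(t$parent_id %in% t$term_id)
  for (id in t$term_id[missing_parent]) {
    v <- c(v, list(viol("unknown_parent", id, "parent id does not exist")))
  }
  lev <- compute_levels(t)
  unreachable <- is.na(lev) & !missing_parent
  for (id in t$term_id[unreachable]) {
    v <- c(v, list(viol(
      "orphan_or_cycle", id, "term is not reachable from the root"
    )))
  }
  for (id in t$term_id[!is.na(lev) & lev > 4L]) {
    v <- c(v, list(viol("level_overflow", id, "deeper than level_4")))
  }
  l1 <- !is.na(lev) & lev == 1L
  bad_l1 <- l1 & !(tolower(t$name) %in% level1_types())
  for (id in t$term_id[bad_l1]) {
    v <- c(v, list(viol(
      "level1_name", id, "level_1 name is not one of the 12 element types"
    )))
  }
  anc <- level1_ancestor(th)
  deep <- which(!is.na(lev) & lev >= 2L & lev <= 4L & !is.na(anc))
  for (i in deep) {
    nm <- t$name[i]
    hy <- regexpr("-", nm, fixed = TRUE)
    pfx <- if (hy > 0L) substr(nm, 1L, hy - 1L) else NA_character_
    if (is.na(pfx) || !pfx %in% prefixes$code) {
      v <- c(v, list(viol(
        "unknown_prefix", t$term_id[i],
        paste0("name \"", nm, "\" does not start with a registered prefix")
      )))
      next
    }
    type <- tolower(anc[i])
    allowed <- tryCatch(prefixes_for_type(type, prefixes),
                        error = function(e) character())
    if (!pfx %in% allowed) {
      v <- c(v, list(viol(
        "prefix_ancestor_mismatch", t$term_id[i],
        paste0("prefix ", pfx, " is not admissible under \"", anc[i], "\"")
      )))
    }
    if (type == "gene silencing elements" && lev[i] >= 3L &&
        !isTRUE(modification_from_name(nm) %in%
                  c("siRNA_sense", "siRNA_antisense", "siRNA_undefined"))) {
      v <- c(v, list(viol(
        "silencing_modifier", t$term_id[i],
        "terms under gene silencing elements need an _siRNA* modifier"
      )))
    }
    if (lev[i] >= 3L) {
      err <- tryCatch({
        parse_name(nm, prefixes, donors, donor_required = TRUE)
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(err)) {
        v <- c(v, list(viol("name_grammar", t$term_id[i], err)))
      }
    }
  }
  out <- dplyr::bind_rows(v)
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      rule = character(), term_id = character(), message = character()
    ))
  }
  rule_order <- c(
    "id_pattern", "duplicate_id", "duplicate_name", "root", "unknown_parent",
    "orphan_or_cycle", "level_overflow", "level1_name", "unknown_prefix",
    "prefix_ancestor_mismatch", "silencing_modifier", "name_grammar"
  )
  out$rule <- factor(out$rule, levels = rule_order)
  out <- dplyr::arrange(out, .data$rule, .data$term_id)
  out$rule <- as.character(out$rule)
  out
}
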