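# Reader and writer for the OBO 1.2 flat-file dialect the vocabulary is
# exchanged in. Writing is deterministic (stanzas sorted by term id, tags
# in fixed order) so that a write -> read -> write cycle is byte-stable;
# reading accepts the printed variants seen in the literature ("e: 0000415"
# with a space, escaped or plain colons in trait xrefs, Donor targets with
# spaces or underscores).

obo_escape_text <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  gsub("\"", "\\\"", x, fixed = TRUE)
}

obo_escape_ref <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub(",", "\\,", x, fixed = TRUE)
  x <- gsub("[", "\\[", x, fixed = TRUE)
  gsub("]", "\\]", x, fixed = TRUE)
}

obo_unescape <- function(x) {
  gsub("\\\\(.)", "\\1", x)
}

# parse a leading quoted string with backslash escapes; returns the
# unescaped text and the remainder after the closing quote
parse_quoted <- function(value, where = "") {
  chars <- strsplit(value, "", fixed = TRUE)[[1]]
  if (length(chars) == 0L || chars[1] != "\"") {
    rlang::abort(paste0("expected a quoted string", where))
  }
  out <- character()
  i <- 2L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "\\" && i < length(chars)) {
      out <- c(out, chars[i + 1L])
      i <- i + 2L
    } else if (ch == "\"") {
      return(list(
        text = paste(out, collapse = ""),
        rest = substr(value, i + 1L, nchar(value))
      ))
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  rlang::abort(paste0("unterminated quoted string", where))
}

split_unescaped <- function(s, sep = ",") {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  parts <- character()
  cur <- character()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "\\" && i < length(chars)) {
      cur <- c(cur, ch, chars[i + 1L])
      i <- i + 2L
    } else if (ch == sep) {
      parts <- c(parts, paste(cur, collapse = ""))
      cur <- character()
      i <- i + 1L
    } else {
      cur <- c(cur, ch)
      i <- i + 1L
    }
  }
  c(parts, paste(cur, collapse = ""))
}

normalize_trait_id <- function(x) {
  x <- obo_unescape(x)
  sub("^t:[[:space:]]+", "t:", trimws(x))
}

#' Read a thesaurus from an OBO flat file
#'
#' Parses `[Term]` stanzas into the term table: `def:` quoted text plus
#' bracketed citations, `comment:`, `synonym:` quoted text, `is_a:` parent
#' links (the trailing `! name` comment is ignored), `xref: BCH:<n>`,
#' `xref: Trait:t:<n>` (escaped colon accepted, optional quoted trait
#' label), `xref: Donor:<organism>` (underscores or spaces), other xrefs
#' and unknown tags preserved verbatim. Stanzas of other types (e.g.
#' `[Typedef]`) are preserved unparsed and re-emitted on write.
#'
#' @param file path to an OBO file (UTF-8).
#' @param text alternatively, the document as a character vector of lines
#'   (or one string with embedded newlines).
#' @return A `gmo_thesaurus`.
#' @export
read_obo <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  }
  lines <- sub("\r$", "", lines)
  stanza_starts <- grep("^\\[", lines)
  header_end <- if (length(stanza_starts)) stanza_starts[1] - 1L else length(lines)
  header <- lines[seq_len(header_end)]
  header <- header[nzchar(trimws(header))]
  meta <- character()
  for (ln in header) {
    m <- regmatches(ln, regexec("^([A-Za-z_0-9-]+):[[:space:]]*(.*)$", ln))[[1]]
    if (length(m) != 3) {
      rlang::abort(paste0("malformed header line: ", ln))
    }
    meta[m[2]] <- m[3]
  }
  rows <- list()
  extra_stanzas <- character()
  idx <- stanza_starts
  bounds <- c(idx, length(lines) + 1L)
  for (k in seq_along(idx)) {
    start <- idx[k]
    end <- bounds[k + 1L] - 1L
    body <- lines[start:end]
    if (!identical(trimws(lines[start]), "[Term]")) {
      extra_stanzas <- c(extra_stanzas, body[nzchar(trimws(body))])
      next
    }
    rows <- c(rows, list(parse_term_stanza(
      body[-1L], line_offset = start
    )))
  }
  ids <- purrr::map_chr(rows, "term_id")
  if (anyDuplicated(ids)) {
    rlang::abort(paste0(
      "duplicate term id: ", ids[duplicated(ids)][1]
    ))
  }
  parents <- purrr::map_chr(rows, "parent_id")
  missing <- setdiff(parents[!is.na(parents)], ids)
  if (length(missing)) {
    rlang::abort(paste0(
      "is_a target does not exist: ", paste(missing, collapse = ", ")
    ))
  }
  terms <- if (length(rows)) {
    tibble::tibble(
      term_id = vapply(rows, `[[`, "", "term_id"),
      name = vapply(rows, `[[`, "", "name"),
      parent_id = vapply(rows, `[[`, "", "parent_id"),
      definition = vapply(rows, `[[`, "", "definition"),
      def_refs = lapply(rows, `[[`, "def_refs"),
      comment = vapply(rows, `[[`, "", "comment"),
      synonyms = lapply(rows, `[[`, "synonyms"),
      trait_refs = lapply(rows, `[[`, "trait_refs"),
      trait_labels = lapply(rows, `[[`, "trait_labels"),
      bch_id = vapply(rows, `[[`, NA_integer_, "bch_id"),
      donor = vapply(rows, `[[`, "", "donor"),
      other_xrefs = lapply(rows, `[[`, "other_xrefs"),
      extra_tags = lapply(rows, `[[`, "extra_tags")
    )
  } else {
    NULL
  }
  th <- gmo_thesaurus(terms, metadata = meta)
  th$extra_stanzas <- as.character(extra_stanzas)
  th
}

parse_term_stanza <- function(body, line_offset = 0L) {
  r <- list(
    term_id = NA_character_, name = NA_character_, parent_id = NA_character_,
    definition = NA_character_, def_refs = character(),
    comment = NA_character_, synonyms = character(),
    trait_refs = character(), trait_labels = character(),
    bch_id = NA_integer_, donor = NA_character_,
    other_xrefs = character(), extra_tags = character()
  )
  for (j in seq_along(body)) {
    ln <- body[j]
    if (!nzchar(trimws(ln))) next
    m <- regmatches(ln, regexec("^([A-Za-z_0-9-]+):[[:space:]]*(.*)$", ln))[[1]]
    if (length(m) != 3) {
      rlang::abort(paste0(
        "malformed tag line ", line_offset + j, ": ", ln
      ))
    }
    tag <- m[2]
    value <- m[3]
    if (tag == "id") {
      r$term_id <- normalize_eid(value)
    } else if (tag == "name") {
      r$name <- value
    } else if (tag == "def") {
      q <- parse_quoted(value, paste0(" on line ", line_offset + j))
      r$definition <- q$text
      rest <- trimws(q$rest)
      if (grepl("^\\[", rest)) {
        inner <- sub("^\\[", "", sub("\\][^]]*$", "", rest))
        if (nzchar(trimws(inner))) {
          r$def_refs <- obo_unescape(trimws(split_unescaped(inner)))
        }
      }
    } else if (tag == "comment") {
      r$comment <- value
    } else if (tag == "synonym") {
      q <- parse_quoted(value, paste0(" on line ", line_offset + j))
      r$synonyms <- c(r$synonyms, q$text)
    } else if (tag == "is_a") {
      target <- sub("!.*$", "", value)
      r$parent_id <- normalize_eid(target)
    } else if (tag == "xref") {
      if (grepl("^BCH:[[:space:]]*[0-9]+$", value)) {
        r$bch_id <- as.integer(sub("^BCH:[[:space:]]*", "", value))
      } else if (grepl("^Trait:", value)) {
        rest <- sub("^Trait:", "", value)
        label <- NA_character_
        qpos <- regexpr("\"", rest, fixed = TRUE)
        if (qpos > 0L) {
          label <- parse_quoted(substr(rest, qpos, nchar(rest)))$text
          rest <- substr(rest, 1L, qpos - 1L)
        }
        r$trait_refs <- c(r$trait_refs, normalize_trait_id(rest))
        r$trait_labels <- c(r$trait_labels, label)
      } else if (grepl("^Donor:", value)) {
        r$donor <- gsub("_", " ", trimws(sub("^Donor:", "", value)))
      } else {
        r$other_xrefs <- c(r$other_xrefs, value)
      }
    } else {
      r$extra_tags <- c(r$extra_tags, ln)
    }
  }
  if (is.na(r$term_id)) {
    rlang::abort(paste0(
      "term stanza starting at line ", line_offset, " has no id"
    ))
  }
  r
}

#' Write a thesaurus to the OBO flat-file dialect
#'
#' Output is deterministic: header in stored order, stanzas sorted by term
#' id, tags in fixed order (id, name, def, comment, synonym, is_a, xref,
#' preserved extra tags). `is_a` lines carry a `! <parent name>` comment;
#' trait xrefs are written with the escaped colon (`Trait:t\:0000006`);
#' Donor targets use underscores for spaces. `read_obo(write_obo(th))`
#' reproduces `th` exactly and a second write is byte-identical.
#'
#' @param th a `gmo_thesaurus`.
#' @param file optional path to write to.
#' @return Invisibly, the document as a character vector of lines.
#' @export
write_obo <- function(th, file = NULL) {
  stopifnot(inherits(th, "gmo_thesaurus"))
  t <- th$terms
  name_of <- stats::setNames(t$name, t$term_id)
  out <- paste0(names(th$metadata), ": ", unname(th$metadata))
  for (i in seq_len(nrow(t))) {
    out <- c(out, "", "[Term]", paste0("id: ", t$term_id[i]),
             paste0("name: ", t$name[i]))
    if (!is.na(t$definition[i])) {
      refs <- t$def_refs[[i]]
      out <- c(out, paste0(
        "def: \"", obo_escape_text(t$definition[i]), "\" [",
        paste(obo_escape_ref(refs), collapse = ", "), "]"
      ))
    }
    if (!is.na(t$comment[i])) {
      out <- c(out, paste0("comment: ", t$comment[i]))
    }
    for (syn in t$synonyms[[i]]) {
      out <- c(out, paste0(
        "synonym: \"", obo_escape_text(syn), "\" EXACT []"
      ))
    }
    if (!is.na(t$parent_id[i])) {
      out <- c(out, paste0(
        "is_a: ", t$parent_id[i], " ! ", unname(name_of[t$parent_id[i]])
      ))
    }
    if (!is.na(t$bch_id[i])) {
      out <- c(out, paste0("xref: BCH:", t$bch_id[i]))
    }
    traits <- t$trait_refs[[i]]
    labels <- t$trait_labels[[i]]
    for (k in seq_along(traits)) {
      line <- paste0("xref: Trait:", sub(":", "\\\\:", traits[k]))
      if (length(labels) >= k && !is.na(labels[k])) {
        line <- paste0(line, " \"", obo_escape_text(labels[k]), "\"")
      }
      out <- c(out, line)
    }
    if (!is.na(t$donor[i])) {
      out <- c(out, paste0("xref: Donor:", gsub(" ", "_", t$donor[i])))
    }
    for (x in t$other_xrefs[[i]]) {
      out <- c(out, paste0("xref: ", x))
    }
    out <- c(out, t$extra_tags[[i]])
  }
  extra <- th$extra_stanzas
  if (!is.null(extra) && length(extra)) {
    out <- c(out, "", extra)
  }
  if (!is.null(file)) {
    con <- file(file, open = "wb")
    on.exit(close(con))
    writeLines(out, con, sep = "\n", useBytes = FALSE)
  }
  invisible(out)
}

#' Flatten a thesaurus to a spreadsheet-friendly table
#'
#' @param th a `gmo_thesaurus`.
#' @param file optional path; when given, the table is written as TSV.
#' @return A tibble with columns `term_id`, `level`, `name`, `parent_id`,
#'   `donor`, `bch_id`, `traits`, `synonyms` (multi-valued fields joined
#'   with `|`).
#' @export
export_tsv <- function(th, file = NULL) {
  t <- th$terms
  out <- tibble::tibble(
    term_id = t$term_id,
    level = t$level,
    name = t$name,
    parent_id = t$parent_id,
    donor = t$donor,
    bch_id = t$bch_id,
    traits = purrr::map_chr(t$trait_refs, paste, collapse = "|"),
    synonyms = purrr::map_chr(t$synonyms, paste, collapse = "|")
  )
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE, na = "",
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  out
}
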