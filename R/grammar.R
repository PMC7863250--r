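# Element designations below level_2 follow the syntax XX-YYYY-ZZZZZ:
# an element-type prefix, an element abbreviation (the stem, which may
# itself contain hyphens), an optional modifier suffix on the stem, and a
# donor-organism code. Because stems may contain hyphens, parsing anchors
# on the FIRST hyphen (prefix) and accepts the segment after the LAST
# hyphen as donor only when it is a registry key.

MODIFIER_TOKENS <- c(
  genome_edited   = "_genome_edited",
  siRNA_antisense = "_siRNAas",
  siRNA_sense     = "_siRNAs",
  siRNA_undefined = "_siRNAu"
)

# characters the naming rules replace with "_": the closed set named by the
# convention (".", "/", acute accent) plus its typographic variants (prime,
# apostrophe) and whitespace
SPECIAL_CHAR_RE <- "[./'\u00b4\u2032[:space:]]"
GREEK_RE <- "[\u0370-\u03ff]"
UTR_RE <- "[[:space:]_]*[35][[:space:]]*[\u2032\u00b4']?[[:space:]_]*UTR[[:space:]]*"

strip_modifier <- function(stem) {
  for (mod in names(MODIFIER_TOKENS)) {
    tok <- MODIFIER_TOKENS[[mod]]
    if (endsWith(stem, tok)) {
      return(list(
        stem = substr(stem, 1L, nchar(stem) - nchar(tok)),
        modifier = mod
      ))
    }
  }
  list(stem = stem, modifier = NA_character_)
}

modifier_token <- function(modifier) {
  ifelse(is.na(modifier), "", unname(MODIFIER_TOKENS[modifier]))
}

# Split one designation without raising: returns prefix, raw stem (modifier
# still attached), modifier, donor and a vector of problems.
split_name <- function(text, prefixes, donors) {
  problems <- character()
  hy <- regexpr("-", text, fixed = TRUE)
  if (hy < 0L || hy == nchar(text)) {
    return(list(
      prefix = NA_character_, stem = NA_character_,
      modifier = NA_character_, donor = NA_character_,
      problems = "no prefix separator"
    ))
  }
  prefix <- substr(text, 1L, hy - 1L)
  rest <- substr(text, hy + 1L, nchar(text))
  if (!prefix %in% prefixes$code) {
    problems <- c(problems, paste0("unknown prefix: ", prefix))
  }
  donor <- NA_character_
  stem <- rest
  last_hy <- max(gregexpr("-", rest, fixed = TRUE)[[1]])
  if (last_hy > 0L) {
    cand <- substr(rest, last_hy + 1L, nchar(rest))
    if (cand %in% donors$code) {
      donor <- cand
      stem <- substr(rest, 1L, last_hy - 1L)
    }
  }
  sm <- strip_modifier(stem)
  if (!nzchar(sm$stem)) {
    problems <- c(problems, "empty stem")
  }
  list(
    prefix = prefix, stem = sm$stem, modifier = sm$modifier,
    donor = donor, problems = problems
  )
}

#' Parse element designations
#'
#' Decomposes designations of the form `XX-YYYY-ZZZZZ` into element-type
#' prefix, stem, optional modifier suffix and optional donor code. The text
#' is split at the first hyphen (prefix); the segment after the last hyphen
#' is taken as donor only if it is a key of the donor registry, otherwise it
#' stays part of the stem (stems such as `beta-gal` legally contain
#' hyphens). Recognized trailing modifier tokens (`_genome_edited`,
#' `_siRNAs`, `_siRNAas`, `_siRNAu`) are stripped from the stem and
#' reported in the `modifier` column.
#'
#' @param text character vector of designations.
#' @param prefixes prefix registry, see [default_prefix_registry()].
#' @param donors donor registry, see [default_donor_registry()].
#' @param donor_required error when no registry-matching donor segment is
#'   present (the rule for level_3/level_4 thesaurus terms).
#' @return A tibble with columns `name`, `prefix`, `stem`, `modifier`,
#'   `donor`; one row per input.
#' @seealso [compose_name()] for the inverse, [lint_name()] for
#'   diagnostics instead of errors.
#' @export
#' @examples
#' parse_name(c("CS-bar-STRHY", "CS-ppo5_genome_edited-SOLTU"))
parse_name <- function(text, prefixes = default_prefix_registry(),
                       donors = default_donor_registry(),
                       donor_required = FALSE) {
  stopifnot(is.character(text), length(text) > 0L, all(nzchar(text)))
  rows <- purrr::map(text, function(nm) {
    p <- split_name(nm, prefixes, donors)
    problems <- p$problems
    if (donor_required && is.na(p$donor)) {
      problems <- c(problems, "no registry-matching donor segment")
    }
    if (!is.na(p$stem) && grepl(SPECIAL_CHAR_RE, p$stem)) {
      problems <- c(problems, "stem contains forbidden characters")
    }
    if (!is.na(p$stem) && grepl(GREEK_RE, p$stem)) {
      problems <- c(problems, "stem contains Greek letters")
    }
    if (length(problems)) {
      rlang::abort(paste0(
        "cannot parse \"", nm, "\": ", paste(problems, collapse = "; ")
      ))
    }
    tibble::tibble(
      name = nm, prefix = p$prefix, stem = p$stem,
      modifier = p$modifier, donor = p$donor
    )
  })
  dplyr::bind_rows(rows)
}

#' Compose element designations from parts
#'
#' The inverse of [parse_name()]: `compose_name(parse_name(x))` returns the
#' canonical form of `x`.
#'
#' @param parts a data frame with columns `prefix`, `stem`, and optionally
#'   `modifier` and `donor` (as returned by [parse_name()]), or a character
#'   vector of prefixes when the remaining parts are given separately.
#' @param stem,modifier,donor used when `parts` is a character vector of
#'   prefix codes; recycled to a common length.
#' @param prefixes,donors registries used to validate the parts.
#' @return Character vector of designations.
#' @export
#' @examples
#' compose_name("P", "ubi1", donor = "MAIZE")
compose_name <- function(parts, stem = NULL, modifier = NA_character_,
                         donor = NA_character_,
                         prefixes = default_prefix_registry(),
                         donors = default_donor_registry()) {
  if (is.data.frame(parts)) {
    df <- parts
    if (!"modifier" %in% names(df)) df$modifier <- NA_character_
    if (!"donor" %in% names(df)) df$donor <- NA_character_
  } else {
    df <- tibble::tibble(
      prefix = parts, stem = stem, modifier = modifier, donor = donor
    )
  }
  ok_prefix <- df$prefix %in% prefixes$code
  ok_stem <- !is.na(df$stem) & nzchar(df$stem) &
    !grepl(SPECIAL_CHAR_RE, df$stem) & !grepl(GREEK_RE, df$stem)
  ok_mod <- is.na(df$modifier) | df$modifier %in% names(MODIFIER_TOKENS)
  ok_donor <- is.na(df$donor) | df$donor %in% donors$code
  bad <- !(ok_prefix & ok_stem & ok_mod & ok_donor)
  if (any(bad)) {
    rlang::abort(paste0(
      "invalid name parts in row(s) ", paste(which(bad), collapse = ", ")
    ))
  }
  paste0(
    df$prefix, "-", df$stem, modifier_token(df$modifier),
    ifelse(is.na(df$donor), "", paste0("-", df$donor))
  )
}

# species abbreviation found fused to the start of a stem, or NULL
leading_species_abbrev <- function(stem, species_abbrev) {
  if (startsWith(stem, "CP4")) {
    return(NULL)  # the strain CP4 is always retained in the stem
  }
  codes <- names(species_abbrev)
  codes <- codes[order(-nchar(codes))]
  for (code in codes) {
    if (startsWith(stem, code) && nchar(stem) > nchar(code) &&
        grepl("^[A-Z0-9]", substr(stem, nchar(code) + 1L, nchar(code) + 1L))) {
      return(code)
    }
  }
  NULL
}

apply_case <- function(x, case_overrides) {
  out <- tolower(x)
  for (ov in case_overrides[order(-nchar(case_overrides))]) {
    pat <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", ov)
    out <- gsub(pat, ov, out, ignore.case = TRUE)
  }
  out
}

# One pass of the stem-normalization pipeline; returns each intermediate
# stage so the linter can attribute changes to rules.
normalize_stages <- function(raw, donor, case_overrides, species_abbrev) {
  s0 <- raw
  s1 <- trimws(gsub(UTR_RE, "", s0))
  stripped_code <- NULL
  s2 <- s1
  ab <- leading_species_abbrev(s1, species_abbrev)
  # strip only when the abbreviation denotes the declared donor; never on
  # capitalization alone
  if (!is.null(ab) && !is.null(donor) && !is.na(donor) &&
      identical(unname(species_abbrev[[ab]]), donor)) {
    s2 <- substr(s1, nchar(ab) + 1L, nchar(s1))
    stripped_code <- ab
  }
  greek <- greek_table()
  s3 <- s2
  if (grepl(GREEK_RE, s3)) {
    for (g in names(greek)) {
      s3 <- gsub(g, greek[[g]], s3, fixed = TRUE)
    }
  }
  s4 <- gsub("_+", "_", gsub(SPECIAL_CHAR_RE, "_", s3))
  s4 <- gsub("^_+|_+$", "", s4)
  s5 <- apply_case(s4, case_overrides)
  list(
    stages = c(s0 = s0, s1 = s1, s2 = s2, s3 = s3, s4 = s4, s5 = s5),
    stripped_code = stripped_code
  )
}

#' Normalize an element-abbreviation stem
#'
#' Applies the naming rules for the middle (`YYYY`) part of a designation,
#' in order: (1) 3'/5' UTR designators are removed (redundant with the `T-`
#' or `P-` prefix); (2) a leading genus-species abbreviation denoting the
#' donor is stripped (`AtAHAS` with donor `ARATH` becomes `ahas`), except
#' the strain token `CP4`, which is always retained; (3) Greek letters are
#' spelled out (`β` becomes `beta`); (4) special characters (`.`,
#' `/`, the acute accent and its typographic variants, whitespace) are
#' replaced by `_`; (5) the stem is lowercased, except spellings listed in
#' `case_overrides`, which are restored.
#'
#' @param raw character vector of raw stems.
#' @param donor donor code(s) the stems belong to (recycled), or `NA`;
#'   species-abbreviation stripping only happens when the abbreviation
#'   denotes this donor.
#' @param case_overrides canonical mixed-case spellings to preserve, see
#'   [default_case_overrides()].
#' @param species_abbrev named vector mapping genus-species abbreviations
#'   to donor codes, see [default_species_abbrev()].
#' @return Character vector of normalized stems. The transformation is
#'   idempotent.
#' @export
#' @examples
#' normalize_stem("AtAHAS", donor = "ARATH")
#' normalize_stem("Cry1Ab/Vip3H", donor = "SYNTH")
normalize_stem <- function(raw, donor = NA_character_,
                           case_overrides = default_case_overrides(),
                           species_abbrev = default_species_abbrev()) {
  stopifnot(is.character(raw), all(nzchar(raw)))
  donor <- rep_len(donor, length(raw))
  out <- purrr::map2_chr(raw, donor, function(r, d) {
    st <- normalize_stages(r, d, case_overrides, species_abbrev)
    res <- unname(st$stages[["s5"]])
    if (!nzchar(res)) {
      rlang::abort(paste0("stem \"", r, "\" is empty after normalization"))
    }
    res
  })
  out
}

#' Normalize a full element designation to its canonical form
#'
#' Parses leniently, normalizes the stem, and recomposes. When the
#' designation carries no donor segment, the donor is taken from the
#' `donor` argument or, failing that, inferred from a leading genus-species
#' abbreviation in the stem (so `"CS-AtAHAS"` canonicalizes to
#' `"CS-ahas-ARATH"` with no donor supplied).
#'
#' @inheritParams parse_name
#' @param donor fallback donor code(s) for designations without a donor
#'   segment (recycled).
#' @inheritParams normalize_stem
#' @return Character vector of canonical designations.
#' @export
#' @examples
#' normalize_name("P-ZmUbi1")
#' normalize_name("CS-AtAHAS")
normalize_name <- function(text, donor = NA_character_,
                           prefixes = default_prefix_registry(),
                           donors = default_donor_registry(),
                           case_overrides = default_case_overrides(),
                           species_abbrev = default_species_abbrev()) {
  stopifnot(is.character(text), all(nzchar(text)))
  donor <- rep_len(donor, length(text))
  purrr::map2_chr(text, donor, function(nm, dn) {
    p <- split_name(nm, prefixes, donors)
    if (length(p$problems)) {
      rlang::abort(paste0(
        "cannot normalize \"", nm, "\": ", paste(p$problems, collapse = "; ")
      ))
    }
    eff_donor <- p$donor
    if (is.na(eff_donor)) eff_donor <- dn
    if (is.na(eff_donor)) {
      ab <- leading_species_abbrev(p$stem, species_abbrev)
      if (!is.null(ab)) eff_donor <- unname(species_abbrev[[ab]])
    }
    stem <- normalize_stem(p$stem, eff_donor, case_overrides, species_abbrev)
    compose_name(p$prefix, stem, p$modifier, eff_donor,
                 prefixes = prefixes, donors = donors)
  })
}

lint_rule_messages <- c(
  no_prefix = "no element-type prefix separator",
  unknown_prefix = "prefix is not in the prefix registry",
  utr_designator = "3'/5' UTR designator is redundant with the prefix",
  species_abbreviation =
    "embedded species abbreviation belongs in the donor segment",
  greek_letter = "Greek letters must be spelled out",
  special_character = "special characters are replaced by '_'",
  nonstandard_character =
    "character outside the naming alphabet; no automatic replacement",
  letter_case = "stems are lowercase unless the abbreviation is canonical",
  missing_donor = "no registry-matching donor segment"
)

#' Lint element designations against the naming rules
#'
#' Returns machine-readable diagnostics, one row per violated rule, each
#' with the rule id, the offending span and the suggested canonical
#' replacement for the whole designation. An empty result means the text is
#' already canonical. When a species abbreviation is stripped, the
#' lowercasing of the remaining stem is part of the same convention and is
#' folded into that single diagnostic.
#'
#' @inheritParams normalize_name
#' @param donor_required add a `missing_donor` diagnostic for designations
#'   without a donor segment that cannot be inferred.
#' @return A tibble with columns `name`, `rule`, `span`, `message`,
#'   `replacement` (`NA` when no automatic replacement exists).
#' @export
#' @examples
#' lint_name("CS-AtAHAS")
#' lint_name("P-ubi1-MAIZE")  # canonical: zero rows
lint_name <- function(text, donor = NA_character_,
                      prefixes = default_prefix_registry(),
                      donors = default_donor_registry(),
                      case_overrides = default_case_overrides(),
                      species_abbrev = default_species_abbrev(),
                      donor_required = FALSE) {
  stopifnot(is.character(text), all(nzchar(text)))
  donor <- rep_len(donor, length(text))
  diag_row <- function(nm, rule, span, replacement) {
    tibble::tibble(
      name = nm, rule = rule, span = span,
      message = unname(lint_rule_messages[rule]),
      replacement = replacement
    )
  }
  rows <- purrr::map2(text, donor, function(nm, dn) {
    p <- split_name(nm, prefixes, donors)
    if ("no prefix separator" %in% p$problems) {
      return(diag_row(nm, "no_prefix", nm, NA_character_))
    }
    if (any(grepl("^unknown prefix", p$problems))) {
      return(diag_row(nm, "unknown_prefix", p$prefix, NA_character_))
    }
    eff_donor <- p$donor
    if (is.na(eff_donor)) eff_donor <- dn
    if (is.na(eff_donor)) {
      ab <- leading_species_abbrev(p$stem, species_abbrev)
      if (!is.null(ab)) eff_donor <- unname(species_abbrev[[ab]])
    }
    st <- normalize_stages(p$stem, eff_donor, case_overrides, species_abbrev)
    s <- st$stages
    canonical <- if (nzchar(s[["s5"]])) {
      compose_name(p$prefix, unname(s[["s5"]]), p$modifier, eff_donor,
                   prefixes = prefixes, donors = donors)
    } else {
      NA_character_
    }
    out <- list()
    if (s[["s1"]] != s[["s0"]]) {
      span <- regmatches(s[["s0"]], regexpr(UTR_RE, s[["s0"]]))
      out <- c(out, list(diag_row(nm, "utr_designator", span, canonical)))
    }
    if (!is.null(st$stripped_code)) {
      out <- c(out, list(
        diag_row(nm, "species_abbreviation", st$stripped_code, canonical)
      ))
    }
    if (s[["s3"]] != s[["s2"]]) {
      span <- paste(
        regmatches(s[["s2"]], gregexpr(GREEK_RE, s[["s2"]]))[[1]],
        collapse = ""
      )
      out <- c(out, list(diag_row(nm, "greek_letter", span, canonical)))
    }
    if (s[["s4"]] != s[["s3"]]) {
      span <- paste(
        regmatches(s[["s3"]], gregexpr(SPECIAL_CHAR_RE, s[["s3"]]))[[1]],
        collapse = ""
      )
      out <- c(out, list(diag_row(nm, "special_character", span, canonical)))
    }
    odd <- regmatches(s[["s4"]], gregexpr("[^A-Za-z0-9_-]", s[["s4"]]))[[1]]
    if (length(odd)) {
      out <- c(out, list(diag_row(
        nm, "nonstandard_character", paste(odd, collapse = ""), NA_character_
      )))
    }
    if (is.null(st$stripped_code) && s[["s5"]] != s[["s4"]]) {
      out <- c(out, list(diag_row(nm, "letter_case", s[["s4"]], canonical)))
    }
    if (donor_required && is.na(eff_donor)) {
      out <- c(out, list(diag_row(nm, "missing_donor", nm, NA_character_)))
    }
    dplyr::bind_rows(out)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      name = character(), rule = character(), span = character(),
      message = character(), replacement = character()
    )
  }
  out
}
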