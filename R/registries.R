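#' Element-type prefix registry
#'
#' The registry of one- or two-letter uppercase prefixes that open every
#' element designation below level_1 and encode the element type
#' (`CS` = coding sequence, `P` = promoter, ...).
#'
#' @param extra optional tibble with columns `code`, `element_type` appended
#'   to the default rows (codes must not clash).
#' @return A tibble with columns `code` and `element_type`.
#' @export
#' @examples
#' default_prefix_registry()
default_prefix_registry <- function(extra = NULL) {
  reg <- tibble::tibble(
    code = c("CS", "E", "I", "L", "O", "P", "R", "T", "TP", "V"),
    element_type = c(
      "coding sequence", "enhancer", "intron", "leader", "other sequence",
      "promoter", "regulatory element other than P, T, I, L or TP",
      "terminator", "transit peptide", "vector fragment"
    )
  )
  if (!is.null(extra)) {
    extra <- tibble::as_tibble(extra)
    if (any(extra$code %in% reg$code)) {
      rlang::abort("extra prefix codes clash with the default registry")
    }
    reg <- dplyr::bind_rows(reg, extra)
  }
  if (anyDuplicated(reg$code) || !all(grepl("^[A-Z]{1,2}$", reg$code))) {
    rlang::abort("prefix codes must be unique, 1-2 uppercase letters")
  }
  reg
}

#' The twelve controlled level_1 element-type names
#'
#' Level_1 of the thesaurus is a fixed controlled list of general element
#' types. Comparison elsewhere in the package is case-insensitive
#' (names are normalized to lowercase).
#'
#' @return A character vector of length 12.
#' @export
level1_types <- function() {
  c(
    "coding sequence", "enhancer", "gene silencing elements",
    "genomic sequence", "intron", "leader", "promoter",
    "other regulatory elements", "terminator", "transit peptide",
    "unknown origin", "vector fragment"
  )
}

#' Map a level_1 type to the prefix codes admissible under it
#'
#' Ten prefixes serve twelve level_1 types: "genomic sequence" and
#' "unknown origin" share the catch-all `O` with "other sequence", and
#' gene-silencing terms carry the prefix of the silenced element type
#' together with an `_siRNA*` modifier, so any registered prefix is
#' admissible there (the modifier is checked separately).
#'
#' @param type a level_1 type name (case-insensitive).
#' @param prefixes prefix registry tibble.
#' @return Character vector of admissible prefix codes.
#' @export
prefixes_for_type <- function(type, prefixes = default_prefix_registry()) {
  type <- tolower(type)
  direct <- c(
    "coding sequence" = "CS", "enhancer" = "E", "intron" = "I",
    "leader" = "L", "promoter" = "P", "terminator" = "T",
    "transit peptide" = "TP", "vector fragment" = "V",
    "other regulatory elements" = "R"
  )
  if (type %in% names(direct)) {
    return(unname(direct[[type]]))
  }
  if (type %in% c("other sequence", "genomic sequence", "unknown origin")) {
    return("O")
  }
  if (type == "gene silencing elements") {
    return(prefixes$code)
  }
  rlang::abort(paste0("unknown level_1 type: ", type))
}

#' Donor-organism code registry
#'
#' Maps the uppercase mnemonic donor codes used in the ZZZZZ segment of an
#' element designation to source organisms. Species codes follow the
#' UniProt controlled-vocabulary mnemonics (ARATH, MAIZE, ...); virus codes
#' are the acronyms of the plant-virus literature and may be mixed case
#' (CaMV, FMV); hybrid or synthetic elements use the reserved code SYNTH.
#'
#' @param extra optional tibble with columns `code`, `category`,
#'   `scientific_name` appended to the defaults.
#' @return A tibble with columns `code`, `category`
#'   (one of "species", "virus", "synthetic") and `scientific_name`.
#' @export
#' @examples
#' default_donor_registry()
default_donor_registry <- function(extra = NULL) {
  reg <- tibble::tribble(
    ~code,    ~category,    ~scientific_name,
    "AGABB",  "species",    "Agaricus bisporus",
    "ARATH",  "species",    "Arabidopsis thaliana",
    "BACTK",  "species",    "Bacillus thuringiensis subsp. kurstaki",
    "BACTU",  "species",    "Bacillus thuringiensis",
    "BRANA",  "species",    "Brassica napus",
    "ECOLX",  "species",    "Escherichia coli",
    "HORVU",  "species",    "Hordeum vulgare",
    "LYCES",  "species",    "Solanum lycopersicum",
    "MAIZE",  "species",    "Zea mays",
    "ORYSA",  "species",    "Oryza sativa",
    "PEA",    "species",    "Pisum sativum",
    "RHIRD",  "species",    "Rhizobium radiobacter",
    "SOLTU",  "species",    "Solanum tuberosum",
    "SOYBN",  "species",    "Glycine max",
    "STRHY",  "species",    "Streptomyces hygroscopicus",
    "STRVR",  "species",    "Streptomyces viridochromogenes",
    "TOBAC",  "species",    "Nicotiana tabacum",
    "WHEAT",  "species",    "Triticum aestivum",
    "CaMV",   "virus",      "Cauliflower mosaic virus",
    "FMV",    "virus",      "Figwort mosaic virus",
    "SYNTH",  "synthetic",  "synthetic or hybrid construct"
  )
  if (!is.null(extra)) {
    extra <- tibble::as_tibble(extra)
    if (any(extra$code %in% reg$code)) {
      rlang::abort("extra donor codes clash with the default registry")
    }
    reg <- dplyr::bind_rows(reg, extra)
  }
  validate_donor_registry(reg)
  reg
}

validate_donor_registry <- function(reg) {
  stopifnot(all(c("code", "category", "scientific_name") %in% names(reg)))
  if (anyDuplicated(reg$code)) {
    rlang::abort("donor codes must be unique")
  }
  bad_cat <- setdiff(unique(reg$category), c("species", "virus", "synthetic"))
  if (length(bad_cat)) {
    rlang::abort(paste0("unknown donor category: ", paste(bad_cat, collapse = ", ")))
  }
  sp <- reg$code[reg$category == "species"]
  if (!all(grepl("^[A-Z0-9]{2,5}$", sp))) {
    rlang::abort("species donor codes must be uppercase, 2-5 characters")
  }
  syn <- reg$code[reg$category == "synthetic"]
  if (length(syn) && !identical(syn, "SYNTH")) {
    rlang::abort("the synthetic donor code must be exactly SYNTH")
  }
  invisible(reg)
}

#' Read a donor-organism registry from a file
#'
#' Two layouts are accepted and auto-detected per line: the package's own
#' three-column TSV (`CODE<TAB>category<TAB>scientific name`) and the
#' UniProt speclist layout (`CODE KINGDOM TAXID: N=Scientific name`), from
#' which the code and name are taken (category "species"). Blank lines and
#' lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return A registry tibble as from [default_donor_registry()].
#' @export
read_donor_registry <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  rows <- purrr::map(lines, function(ln) {
    if (grepl("\t", ln)) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 3) {
        rlang::abort(paste0("malformed registry line: ", ln))
      }
      tibble::tibble(
        code = trimws(parts[1]), category = trimws(parts[2]),
        scientific_name = trimws(parts[3])
      )
    } else {
      m <- regmatches(
        ln,
        regexec("^([A-Za-z0-9]{2,6})\\s+[A-Z]\\s+\\d+:\\s*N=(.*)$", ln)
      )[[1]]
      if (length(m) != 3) {
        rlang::abort(paste0("unrecognized registry line: ", ln))
      }
      tibble::tibble(
        code = m[2], category = "species", scientific_name = trimws(m[3])
      )
    }
  })
  reg <- dplyr::bind_rows(rows)
  validate_donor_registry(reg)
  reg
}

#' Conventional genus-species abbreviations embedded in legacy element names
#'
#' Legacy designations often carry a two-letter genus-species abbreviation
#' fused to the element abbreviation (AtAHAS, ZmUbi1). The table maps those
#' abbreviations to the donor code they denote, so normalization can strip
#' them and move the information to the donor segment. Stripping is only
#' applied when the abbreviation agrees with the (declared or inferred)
#' donor, never on capitalization alone.
#'
#' @return A named character vector: abbreviation -> donor code.
#' @export
default_species_abbrev <- function() {
  c(
    At = "ARATH", Bn = "BRANA", Gm = "SOYBN", Hv = "HORVU", Le = "LYCES",
    Nt = "TOBAC", Os = "ORYSA", St = "SOLTU", Ta = "WHEAT", Zm = "MAIZE"
  )
}

#' Canonical mixed-case spellings preserved through stem normalization
#'
#' Stems are lowercased unless the commonly used abbreviation is uppercase
#' or mixed case; these spellings are restored after lowercasing, longest
#' match first.
#'
#' @return A character vector of canonical spellings.
#' @export
default_case_overrides <- function() {
  c(
    "cry1Ab10", "cry1Ab", "cry1Ac", "vip3H", "CP4epsps", "rbcS_E9",
    "34S", "35S"
  )
}

# Greek one-letter codes -> spelled-out lowercase names.
greek_table <- function() {
  spelled <- c(
    "alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta", "theta",
    "iota", "kappa", "lambda", "mu", "nu", "xi", "omicron", "pi", "rho",
    "sigma", "tau", "upsilon", "phi", "chi", "psi", "omega"
  )
  lc <- intToUtf8(c(0x3B1:0x3C1, 0x3C3:0x3C9), multiple = TRUE)  # skip final sigma
  uc <- intToUtf8(c(0x391:0x3A1, 0x3A3:0x3A9), multiple = TRUE)
  tab <- c(
    stats::setNames(spelled, lc),
    stats::setNames(spelled, uc),
    stats::setNames("sigma", intToUtf8(0x3C2))  # final sigma
  )
  tab
}
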