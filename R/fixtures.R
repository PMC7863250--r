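# The packaged worked-example thesaurus: the root, the twelve level_1
# element types, and the published example branch terms (glyphosate and
# glufosinate tolerance genes, cry delta-endotoxins, genome-edited
# polyphenol oxidases, the classic viral/agrobacterial promoters and
# terminators) with their synonyms, donors, traits, definitions, citations
# and BCH ids as printed in the source registries. The free-text
# definition and function cells are data and are stored verbatim
# (including their literature citations); known transcription artifacts
# are documented in inst/extdata/fixture-NOTES.md rather than corrected.

#' Build the packaged worked-example thesaurus
#'
#' Deterministically constructs the small thesaurus the package ships for
#' tests and demonstrations: root, the 12 level_1 element types, the
#' published level_2 long names, 16 level_3/level_4 element designations
#' with synonyms, donor annotations, trait references, definitions,
#' citations and BCH identifiers. `CS-bar-STRHY` carries id `e:0000415`
#' under parent `e:0000188`. The builder's output is byte-identical to the
#' checked-in OBO file at `system.file("extdata", "gmo-get-fixture.obo",
#' package = "gmoget")`.
#'
#' @return A `gmo_thesaurus`.
#' @export
#' @examples
#' th <- build_example_thesaurus()
#' glance(th)
build_example_thesaurus <- function() {
  th <- gmo_thesaurus(metadata = c(
    "format-version" = "1.2",
    "date" = "05:02:2021 12:00",
    "default-namespace" = "gmo_genetic_element_thesaurus"
  ))
  th <- add_term(th, "genetic element", term_id = "e:0000000")
  l1 <- level1_types()
  for (i in seq_along(l1)) {
    th <- add_term(th, l1[i], parent_id = "e:0000000",
                   term_id = format_eid(i))
  }
  l1_id <- stats::setNames(format_eid(seq_along(l1)), l1)
  nd <- "\u2013"  # en dash as printed in page ranges
  pr <- "\u2032"  # prime as printed in 3' UTR designators

  # level_2 functional long names
  th <- add_term(th, "CS-5-enolpyruvylshikimate-3-phosphate synthase",
                 parent_id = l1_id[["coding sequence"]],
                 term_id = "e:0000101")
  th <- add_term(th, "CS-crystal delta-endotoxin",
                 parent_id = l1_id[["coding sequence"]],
                 term_id = "e:0000102")
  th <- add_term(th, "CS-polyphenol oxidase",
                 parent_id = l1_id[["coding sequence"]],
                 term_id = "e:0000104")
  th <- add_term(th, "CS-phosphinothricin N-acetyltransferase",
                 parent_id = l1_id[["coding sequence"]],
                 term_id = "e:0000188")
  th <- add_term(th, "P-Figwort mosaic virus",
                 parent_id = l1_id[["promoter"]], term_id = "e:0000110")
  th <- add_term(th, "P-Cauliflower mosaic virus",
                 parent_id = l1_id[["promoter"]], term_id = "e:0000111")
  th <- add_term(th, "P-nopaline synthase",
                 parent_id = l1_id[["promoter"]], term_id = "e:0000112")
  th <- add_term(th, "P-ubiquitin",
                 parent_id = l1_id[["promoter"]], term_id = "e:0000113")
  th <- add_term(th, "T-Cauliflower mosaic virus",
                 parent_id = l1_id[["terminator"]], term_id = "e:0000120")
  th <- add_term(th, "T-nopaline synthase",
                 parent_id = l1_id[["terminator"]], term_id = "e:0000121")
  th <- add_term(th, "T-RuBisCO small subunit",
                 parent_id = l1_id[["terminator"]], term_id = "e:0000122")

  term_comment <- "Terminator (indicates the end of transcription; directs polyadenylation)"
  prom_comment <- "Promoter (directs transcription)"

  th <- add_term(
    th, "CS-CP4epsps-RHIRD", parent_id = "e:0000101", term_id = "e:0000201",
    definition = "5-Enolpyruvylshikimate-3-phosphate synthase gene from Agrobacterium sp. strain CP4.",
    def_refs = paste0("Steinr\u00fccken et al. (1980) Biochem Biophys Res Com. 94:1207", nd, "1212"),
    comment = paste0(
      "Is similar and functionally identical to endogenous plant EPSPS enzymes but has a much-reduced affinity for glyphosate relative to endogenous plant EPSPS. ",
      "Padgette et al. (1996) J Nutr 126:728", nd, "740"
    ),
    synonyms = "aroA", donor = "Agrobacterium tumefaciens ssp. CP4",
    trait_refs = "t:0000030", trait_labels = "Glyphosate tolerance",
    bch_id = 14979L
  )
  th <- add_term(
    th, "CS-cry1Ab_vip3H-SYNTH", parent_id = "e:0000102",
    term_id = "e:0000202",
    definition = "Chimeric gene encoding for the fused protein of Cry1Ab/Vip3H",
    comment = "Confers resistance to lepidopteran such as the Asiatic rice borer Chilo suppressalis and the stem borer Sesamia inferens",
    synonyms = "HJC-1", donor = "Synthetic",
    trait_refs = "t:0000035", trait_labels = "Lepidoptera resistance"
  )
  th <- add_term(
    th, "CS-cry1Ab-BACTU", parent_id = "e:0000102", term_id = "e:0000203",
    definition = "Plant optimized gene encoding for the nature identical (full length) cry1Ab gene of B. thuringiensis ssp. Kurstaki HD-1 strain",
    def_refs = paste0("Fischhoff D et al. (1987) Bio/Technology, 5, 807", nd, "813 (Accession no. A29125)"),
    comment = "The trypsin resistant core of the encoded protein is insecticidal to lepidopteran larvae. It acts by selectively binding to specific sites localized on the lining of the midgut of susceptible insect species. Confers resistance against certain lepidopteran insect pests, including the European Corn Borer (ECB) (Ostrinia nubilalis) and pink borers (Sesamia spp.)",
    synonyms = "cry1Ab", donor = "Bacillus thuringiensis",
    trait_refs = "t:0000035", trait_labels = "Lepidoptera resistance",
    bch_id = 14985L
  )
  th <- add_term(
    th, "CS-cry1Ac-BACTU", parent_id = "e:0000102", term_id = "e:0000204",
    comment = "The trypsin resistant core of the encoded protein is insecticidal to lepidopteran larvae. It acts by selectively binding to specific sites localized on the lining of the midgut of susceptible insect species",
    synonyms = "cry1Ac", donor = "Bacillus thuringiensis ssp. Kurstaki",
    trait_refs = "t:0000035", trait_labels = "Lepidoptera resistance",
    bch_id = 14986L
  )
  th <- add_term(
    th, "CS-bar-STRHY", parent_id = "e:0000188", term_id = "e:0000415",
    definition = "Phosphinothricin acetyltransferase gene derived from the common soil bacterium Streptomyces hygroscopicus a.k.a. bar gene; shares 85 per cent homology at the amino acid level with the pat gene.",
    def_refs = paste0("Thompson et al. (1987) EMBO J. 6:2519", nd, "2523"),
    comment = paste0(
      "Acetylates the primary amino group of L-phosphinothricin (L-PPT; a.k.a. glufosinate) rendering it inactive. ",
      "Wehrmann et al. (1996) Nat Biotechnol. 14:1274", nd, "1278; ENV/JM/MONO(99) 13:1", nd, "26"
    ),
    synonyms = c("Bialaphos resistance", "PAT"),
    donor = "Streptomyces hygroscopicus",
    trait_refs = "t:0000006",
    trait_labels = "Herbicide tolerance > Glufosinate tolerance",
    bch_id = 14972L
  )
  th <- add_term(
    th, "CS-pat-STRVR", parent_id = "e:0000188", term_id = "e:0000206",
    definition = "Phosphinothricin acetyltransferase gene derived from Streptomyces viridochromogenes a.k.a. pat gene; shares 85% homology at the amino acid level with the bar gene.",
    def_refs = paste0("Wohlleben et al. (1988) Gene 70:25", nd, "37"),
    comment = paste0(
      "Acetylates the primary amino group of L-phosphinothricin (L-PPT; a.k.a. glufosinate) rendering it inactive. ",
      "Wehrmann et al. (1996) Nat Biotechnol.14:1274", nd, "1278; ENV/JM/MONO(99) 13:1", nd, "26"
    ),
    synonyms = "Bialaphos resistance",
    donor = "Streptomyces viridochromogenes",
    trait_refs = "t:0000029", trait_labels = "Glufosinate tolerance",
    bch_id = 15002L
  )
  th <- add_term(
    th, "CS-ppo5_genome_edited-SOLTU", parent_id = "e:0000104",
    term_id = "e:0000207",
    definition = "Polyphenol oxidase 5 gene.",
    def_refs = paste0("Thygesen et al. (1995) Plant Physiol. 109:525", nd, "531"),
    comment = "Active in tubers, major cause of enzymatic browning. Loss-of-function mutations in the ppo5 gene result in reduced browning of potato tubers (reduced 'black spot')",
    donor = "Solanum tuberosum",
    trait_refs = "t:0000055", trait_labels = "Reduced black spot bruising"
  )
  th <- add_term(
    th, "CS-ppo_genome_edited-AGABB", parent_id = "e:0000104",
    term_id = "e:0000208",
    definition = "Polyphenol oxidase gene.",
    def_refs = paste0("Wu et al. (2010) Biotechnol Letters 32(10):1439", nd, "1447"),
    comment = "Major cause of enzymatic browning. Loss-of-function mutations in the ppo gene leads to reduced enzymatic browning",
    donor = "Agaricus bisporus",
    trait_refs = "t:0000029", trait_labels = "Glufosinate tolerance"
  )
  th <- add_term(
    th, "P-34S-FMV", parent_id = "e:0000110", term_id = "e:0000210",
    definition = "34S promoter derived from Figwort mosaic virus (FMV).",
    def_refs = c(
      paste0("Shepard et al. (1987) Phytopathology 77:1668", nd, "1673"),
      paste0("Richins et al. (1987); Nucl Acids Res. 15:8451", nd, "8466"),
      "Gowda et al. (1989) J Cell Biochem. 13D (supplement):301"
    ),
    comment = prom_comment,
    synonyms = c("P-34S FMV", "P-35SFMV", "P-CMoVb"),
    donor = "Figwort mosaic virus",
    bch_id = 101507L
  )
  th <- add_term(
    th, "P-35S-CaMV", parent_id = "e:0000111", term_id = "e:0000211",
    definition = "The 35S promoter was isolated from the Cauliflower mosaic virus (CaMV). The element covers the full-length promoter as well as optimized variants of the promoter.",
    def_refs = paste0("Odell JT et al. (1985) Nature 313, 810", nd, "812"),
    comment = "The 35S promoter is a very strong constitutive promoter, resulting in high levels of gene expression in dicot plants. However, it is less effective in monocots, especially in cereals",
    synonyms = c("P-35S", "P-CaMV 35S"),
    donor = "Cauliflower mosaic virus",
    bch_id = 100287L
  )
  th <- add_term(
    th, "P-nos-RHIRD", parent_id = "e:0000112", term_id = "e:0000212",
    definition = "Promoter region of the nopaline synthase gene from Agrobacterium tumefaciens T-DNA.",
    def_refs = c(
      paste0("Bevan et al. (1983) Nucl Acids Res. 11:369", nd, "385"),
      paste0("Fraley et al. (1983) Proc Nat L Acad Sci. 80:4803", nd, "4807")
    ),
    comment = prom_comment,
    synonyms = "pNOS",
    donor = "Agrobacterium tumefaciens",
    bch_id = 100270L
  )
  th <- add_term(
    th, "P-ubi1-MAIZE", parent_id = "e:0000113", term_id = "e:0000213",
    definition = "Promoter region of the polyubiquitin gene from Zea mays.",
    def_refs = paste0("Christensen et al. (1992) Plant Mol Biol. 18: 675", nd, "689"),
    comment = prom_comment,
    synonyms = c("P-ZmUbi1", "P-ubiZM1"),
    donor = "Zea mays",
    bch_id = 100362L
  )
  th <- add_term(
    th, "T-35S-CaMV", parent_id = "e:0000120", term_id = "e:0000220",
    definition = paste0("3", pr, " Transcriptional termination element (3", pr, " UTR) of the 35S gene from Cauliflower mosaic virus."),
    def_refs = paste0("Gardner et al. (1981) Nucleic Acids Res. 9:2871", nd, "2888"),
    comment = term_comment,
    synonyms = c(paste0("3", pr, " 35S"), "35S TERM"),
    donor = "Cauliflower mosaic virus",
    bch_id = 100290L
  )
  th <- add_term(
    th, "T-nos-RHIRD", parent_id = "e:0000121", term_id = "e:0000221",
    definition = paste0("3", pr, " Transcriptional termination element (3", pr, " UTR) of the nopaline synthase gene from Agrobacterium tumefaciens T-DNA."),
    def_refs = c(
      paste0("Bevan et al. (1983) Nucleic Acids Res. 11: 369", nd, "385"),
      paste0("Fraley et al. (1983) Proc Nat L Acad Sci. 80:4803", nd, "4807")
    ),
    comment = term_comment,
    synonyms = c(paste0("3", pr, " nos"), "NOST"),
    donor = "Agrobacterium tumefaciens",
    bch_id = 100269L
  )
  th <- add_term(
    th, "T-rbcS_E9-PEA", parent_id = "e:0000122", term_id = "e:0000222",
    definition = paste0("3", pr, " Transcriptional termination element (3", pr, " UTR) of the rinulose-1,5-bisphosphate carboxylase, small subunit (rbcS E9) gene."),
    def_refs = paste0("Coruzzi et al. (1984) EMBO J. 3:1671", nd, "1679"),
    comment = term_comment,
    synonyms = c("T-RuBisCO SSU", "T-SSU", "T-rbcS-E9"),
    donor = "Pisum sativum",
    bch_id = 101877L
  )
  # level_4 sequence variant
  th <- add_term(
    th, "CS-cry1Ab10-BACTK", parent_id = "e:0000203", term_id = "e:0000300"
  )
  th
}

#' Path of the checked-in fixture OBO file
#'
#' @return File path inside the installed package.
#' @export
fixture_obo_path <- function() {
  system.file("extdata", "gmo-get-fixture.obo", package = "gmoget",
              mustWork = TRUE)
}

random_stem <- function(used, r_digit = 0.5) {
  repeat {
    n_syll <- sample(2:3, 1)
    syll <- paste0(
      sample(c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
               "v", "z"), n_syll, replace = TRUE),
      sample(c("a", "e", "i", "o", "u"), n_syll, replace = TRUE)
    )
    stem <- paste(syll, collapse = "")
    if (stats::runif(1) < r_digit) {
      stem <- paste0(stem, sample(0:9, 1))
    }
    if (!stem %in% used) {
      return(stem)
    }
  }
}

random_words <- function(used) {
  repeat {
    w <- paste(
      replicate(2, random_stem(character(), r_digit = 0)), collapse = " "
    )
    if (!w %in% used) return(w)
  }
}

#' Generate a seeded random thesaurus
#'
#' Builds a structurally valid thesaurus for property tests: the root, the
#' twelve level_1 types, `n_level2` random functional long names spread
#' over the single-prefix branches, `n_level3_per_branch`
#' grammar-conformant element designations per branch (random lowercase
#' stems, donors from the registry, occasional `_genome_edited`
#' modifiers), and level_4 variants at rate `n_level4_rate`. Random
#' synonyms, BCH ids, trait references, donor annotations, definitions and
#' comments exercise serialization. The same seed yields the identical
#' thesaurus.
#'
#' @param seed integer seed.
#' @param n_level2 number of level_2 branch terms.
#' @param n_level3_per_branch level_3 terms under each level_2 term.
#' @param n_level4_rate probability a level_3 term gets a level_4 variant.
#' @param donors,prefixes registries the generated names draw from.
#' @return A `gmo_thesaurus` whose [validate_thesaurus()] report is empty.
#' @export
generate_random_thesaurus <- function(seed, n_level2 = 6,
                                      n_level3_per_branch = 3,
                                      n_level4_rate = 0.2,
                                      donors = default_donor_registry(),
                                      prefixes = default_prefix_registry()) {
  stopifnot(n_level2 >= 1, n_level3_per_branch >= 1,
            n_level4_rate >= 0, n_level4_rate <= 1)
  if (13 + n_level2 * (1 + 2 * n_level3_per_branch) > 9999999) {
    rlang::abort("requested sizes exceed the id space")
  }
  withr::with_seed(seed, {
    l1 <- level1_types()
    rows <- list(list(term_id = format_eid(0), name = "genetic element",
                      parent_id = NA_character_))
    for (i in seq_along(l1)) {
      rows <- c(rows, list(list(
        term_id = format_eid(i), name = l1[i],
        parent_id = format_eid(0)
      )))
    }
    branch_types <- c(
      "coding sequence", "enhancer", "intron", "leader", "promoter",
      "other regulatory elements", "terminator", "transit peptide",
      "vector fragment"
    )
    counter <- 100L
    used_stems <- character()
    used_words <- character()
    syn_pool <- 0L
    bch_pool <- sample(10000:99999, n_level2 * n_level3_per_branch * 2)
    bch_i <- 0L
    mk_extras <- function() {
      out <- list(
        definition = NA_character_, def_refs = character(),
        comment = NA_character_, synonyms = character(),
        trait_refs = character(), trait_labels = character(),
        bch_id = NA_integer_, donor = NA_character_
      )
      if (stats::runif(1) < 0.4) {
        out$definition <- paste("Synthetic definition",
                                random_stem(character()))
        if (stats::runif(1) < 0.5) {
          out$def_refs <- paste("Ref", sample(1900:2099, sample(1:2, 1)))
        }
      }
      if (stats::runif(1) < 0.3) {
        out$comment <- paste("Synthetic function note",
                             random_stem(character()))
      }
      if (stats::runif(1) < 0.4) {
        n_syn <- sample(1:2, 1)
        syn_pool <<- syn_pool + n_syn
        out$synonyms <- sprintf("syn%04d", syn_pool - seq_len(n_syn) + 1L)
      }
      if (stats::runif(1) < 0.3) {
        bch_i <<- bch_i + 1L
        out$bch_id <- bch_pool[bch_i]
      }
      if (stats::runif(1) < 0.3) {
        out$trait_refs <- sprintf("t:%07d", sample(1:999999, 1))
        out$trait_labels <- if (stats::runif(1) < 0.5) {
          paste("Trait", random_stem(character()))
        } else {
          NA_character_
        }
      }
      out
    }
    for (b in seq_len(n_level2)) {
      type <- sample(branch_types, 1)
      pfx <- prefixes_for_type(type, prefixes)
      w <- random_words(used_words)
      used_words <- c(used_words, w)
      l2_id <- format_eid(counter)
      counter <- counter + 1L
      rows <- c(rows, list(list(
        term_id = l2_id, name = paste0(pfx, "-", w),
        parent_id = format_eid(match(type, l1))
      )))
      for (j in seq_len(n_level3_per_branch)) {
        stem <- random_stem(used_stems)
        used_stems <- c(used_stems, stem)
        donor_code <- sample(donors$code, 1)
        modifier <- if (stats::runif(1) < 0.15) "genome_edited" else NA_character_
        nm <- compose_name(pfx, stem, modifier, donor_code,
                           prefixes = prefixes, donors = donors)
        l3_id <- format_eid(counter)
        counter <- counter + 1L
        ex <- mk_extras()
        if (stats::runif(1) < 0.5) {
          ex$donor <- donors$scientific_name[donors$code == donor_code]
        }
        rows <- c(rows, list(c(list(
          term_id = l3_id, name = nm, parent_id = l2_id
        ), ex)))
        if (stats::runif(1) < n_level4_rate) {
          repeat {
            v_stem <- paste0(stem, sample(0:9, 1))
            if (!v_stem %in% used_stems) break
          }
          used_stems <- c(used_stems, v_stem)
          v_nm <- compose_name(pfx, v_stem, NA_character_, donor_code,
                               prefixes = prefixes, donors = donors)
          rows <- c(rows, list(list(
            term_id = format_eid(counter), name = v_nm, parent_id = l3_id
          )))
          counter <- counter + 1L
        }
      }
    }
    chr_col <- function(field) {
      vapply(rows, function(r) r[[field]] %||% NA_character_, "")
    }
    list_col <- function(field) {
      lapply(rows, function(r) as.character(r[[field]] %||% character()))
    }
    terms <- tibble::tibble(
      term_id = chr_col("term_id"),
      name = chr_col("name"),
      parent_id = chr_col("parent_id"),
      definition = chr_col("definition"),
      def_refs = list_col("def_refs"),
      comment = chr_col("comment"),
      synonyms = list_col("synonyms"),
      trait_refs = list_col("trait_refs"),
      trait_labels = list_col("trait_labels"),
      bch_id = vapply(rows, function(r) {
        as.integer(r$bch_id %||% NA_integer_)
      }, NA_integer_),
      donor = chr_col("donor")
    )
    gmo_thesaurus(terms, metadata = c(
      "format-version" = "1.2",
      "default-namespace" = "gmo_genetic_element_thesaurus"
    ))
  })
}

#' Generate seeded random GMO annotations and method assignments
#'
#' GMOs are annotated with uniformly sampled level 3-4 terms; methods
#' target uniformly sampled level 2-4 terms. Per GMO the number of
#' annotated elements is binomial with size 4 and probability
#' `annotation_rate`, so `annotation_rate = 1` guarantees at least one
#' element and `annotation_rate = 0` produces unannotated GMOs (emitted as
#' a single `NA` annotation row).
#'
#' @param seed integer seed.
#' @param th a `gmo_thesaurus` with at least one level_3 term.
#' @param n_gmos,n_methods numbers of GMO records and method assignments.
#' @param annotation_rate per-element annotation probability.
#' @return A list with tibbles `gmos` (`gmo_id`, `element_id`) and
#'   `methods` (`method_id`, `target_id`).
#' @export
generate_random_annotations <- function(seed, th, n_gmos = 20,
                                        n_methods = 10,
                                        annotation_rate = 0.5) {
  t <- th$terms
  pool3 <- t$term_id[!is.na(t$level) & t$level >= 3L]
  pool2 <- t$term_id[!is.na(t$level) & t$level >= 2L]
  if (n_methods > 0 && length(pool2) == 0L) {
    rlang::abort("thesaurus has no level >= 2 terms to target")
  }
  withr::with_seed(seed, {
    gmos <- if (n_gmos == 0L) {
      tibble::tibble(gmo_id = character(), element_id = character())
    } else {
      dplyr::bind_rows(purrr::map(seq_len(n_gmos), function(i) {
        gid <- sprintf("GMO-%03d", i)
        k <- stats::rbinom(1, size = 4, prob = annotation_rate)
        if (k == 0L || length(pool3) == 0L) {
          tibble::tibble(gmo_id = gid, element_id = NA_character_)
        } else {
          tibble::tibble(
            gmo_id = gid,
            element_id = sample(pool3, min(k, length(pool3)))
          )
        }
      }))
    }
    methods <- if (n_methods == 0L) {
      tibble::tibble(method_id = character(), target_id = character())
    } else {
      tibble::tibble(
        method_id = sprintf("M-%03d", seq_len(n_methods)),
        target_id = sample(pool2, n_methods, replace = TRUE)
      )
    }
    list(gmos = gmos, methods = methods)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
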