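test_that("parse_name splits prefix, stem, modifier and donor", {
  cases <- tibble::tribble(
    ~text,                          ~prefix, ~stem,       ~modifier,       ~donor,
    "CS-bar-STRHY",                 "CS",    "bar",       NA_character_,   "STRHY",
    "CS-ppo5_genome_edited-SOLTU",  "CS",    "ppo5",      "genome_edited", "SOLTU",
    "CS-CP4epsps-RHIRD",            "CS",    "CP4epsps",  NA_character_,   "RHIRD",
    "P-ubi1-MAIZE",                 "P",     "ubi1",      NA_character_,   "MAIZE",
    "T-nos-RHIRD",                  "T",     "nos",       NA_character_,   "RHIRD"
  )
  parsed <- parse_name(cases$text)
  expect_identical(parsed$prefix, cases$prefix)
  expect_identical(parsed$stem, cases$stem)
  expect_identical(parsed$modifier, cases$modifier)
  expect_identical(parsed$donor, cases$donor)

  # hyphens are legal inside stems: the donor segment must match the registry
  p <- parse_name("CS-beta-gal")
  expect_identical(p$stem, "beta-gal")
  expect_true(is.na(p$donor))

  expect_error(parse_name("Q-foo-STRHY"), "unknown prefix")
  expect_error(parse_name("CS-beta-gal", donor_required = TRUE),
               "donor")
  expect_error(parse_name("CS--STRHY"), "empty stem")
})

test_that("modifier suffixes are distinguished, including siRNA variants", {
  expect_identical(parse_name("CS-foo_siRNAas-MAIZE")$modifier,
                   "siRNA_antisense")
  expect_identical(parse_name("CS-foo_siRNAs-MAIZE")$modifier, "siRNA_sense")
  expect_identical(parse_name("CS-foo_siRNAu-MAIZE")$modifier,
                   "siRNA_undefined")
})

test_that("compose_name emits canonical designations and round-trips", {
  expect_identical(compose_name("P", "ubi1", donor = "MAIZE"),
                   "P-ubi1-MAIZE")
  expect_identical(
    compose_name("CS", "ppo", "genome_edited", "AGABB"),
    "CS-ppo_genome_edited-AGABB"
  )
  expect_identical(compose_name("T", "nos", donor = "RHIRD"), "T-nos-RHIRD")
  expect_error(compose_name("QQ", "x"), "invalid name parts")

  corpus <- c(
    "CS-bar-STRHY", "CS-ppo5_genome_edited-SOLTU", "CS-beta-gal",
    "P-35S-CaMV", "CS-cry1Ab_vip3H-SYNTH"
  )
  expect_identical(compose_name(parse_name(corpus)), corpus)
})

test_that("normalize_stem applies the published translation rules", {
  expect_identical(normalize_stem("AtAHAS", donor = "ARATH"), "ahas")
  expect_identical(normalize_stem("ZmUbi1", donor = "MAIZE"), "ubi1")
  expect_identical(normalize_stem("Cry1Ab/Vip3H", donor = "SYNTH"),
                   "cry1Ab_vip3H")
  expect_identical(normalize_stem("β-gal"), "beta-gal")
  # CP4 is retained even though it looks like a strain/species marker
  expect_identical(normalize_stem("CP4epsps", donor = "RHIRD"), "CP4epsps")
  # UTR designators disappear
  expect_identical(normalize_stem("nos 3′ UTR", donor = "RHIRD"), "nos")
  # no stripping when the abbreviation contradicts the donor
  expect_identical(normalize_stem("AtAHAS", donor = "MAIZE"), "atahas")
})

test_that("normalize_stem is idempotent", {
  raws <- c("AtAHAS", "ZmUbi1", "Cry1Ab/Vip3H", "β-gal", "CP4epsps",
            "nos 3′ UTR", "rbcS.E9", "Foo/Bar´Baz", "35S")
  donors <- c("ARATH", "MAIZE", "SYNTH", NA, "RHIRD", "RHIRD", "PEA",
              NA, "CaMV")
  once <- normalize_stem(raws, donors)
  twice <- normalize_stem(once, donors)
  expect_identical(twice, once)
})

test_that("normalize_name reproduces the published translations", {
  expect_identical(normalize_name("CS-AtAHAS"), "CS-ahas-ARATH")
  expect_identical(normalize_name("P-ZmUbi1"), "P-ubi1-MAIZE")
  expect_identical(normalize_name("CS-CP4epsps-RHIRD"), "CS-CP4epsps-RHIRD")
})

test_that("lint_name reports one diagnostic per violated rule", {
  d <- lint_name("CS-AtAHAS")
  expect_identical(nrow(d), 1L)
  expect_identical(d$rule, "species_abbreviation")
  expect_identical(d$replacement, "CS-ahas-ARATH")

  expect_identical(nrow(lint_name("P-ubi1-MAIZE")), 0L)
  expect_identical(nrow(lint_name("CS-CP4epsps-RHIRD")), 0L)

  d <- lint_name("T-nos 3′ UTR-RHIRD")
  expect_identical(d$rule, "utr_designator")
  expect_identical(d$replacement, "T-nos-RHIRD")

  d <- lint_name("CS-βgal-ECOLX")
  expect_identical(d$rule, "greek_letter")
  expect_identical(d$replacement, "CS-betagal-ECOLX")

  d <- lint_name("CS-rbcS.E9-PEA")
  expect_true("special_character" %in% d$rule)

  d <- lint_name("P-NOS-RHIRD")
  expect_identical(d$rule, "letter_case")
  expect_identical(d$replacement, "P-nos-RHIRD")

  expect_identical(lint_name("Q-foo-STRHY")$rule, "unknown_prefix")
  expect_true("missing_donor" %in%
                lint_name("CS-bar", donor_required = TRUE)$rule)
})

test_that("every fixture level 3-4 designation is canonical", {
  th <- build_example_thesaurus()
  t <- tidy(th)
  corpus <- t$name[t$level >= 3]
  expect_identical(length(corpus), 16L)
  parsed <- parse_name(corpus, donor_required = TRUE)
  expect_identical(compose_name(parsed), corpus)
  expect_identical(nrow(lint_name(corpus)), 0L)
})

test_that("random trailing segments never pass as donors", {
  set.seed(42)
  donors <- default_donor_registry()
  for (i in 1:50) {
    suffix <- paste(
      sample(c(LETTERS, letters, 0:9), sample(2:6, 1), replace = TRUE),
      collapse = ""
    )
    if (suffix %in% donors$code) next
    p <- parse_name(paste0("CS-stem-", suffix))
    expect_true(is.na(p$donor))
    expect_identical(p$stem, paste0("stem-", suffix))
  }
})
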