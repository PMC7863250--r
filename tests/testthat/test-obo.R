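test_that("read_obo maps stanza tags onto term fields", {
  doc <- c(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: e:0000000",
    "name: genetic element",
    "",
    "[Term]",
    "id: e:0000001",
    "name: coding sequence",
    "is_a: e:0000000 ! genetic element",
    "",
    "[Term]",
    "id: e:0000188",
    "name: CS-phosphinothricin N-acetyltransferase",
    "is_a: e:0000001",
    "",
    "[Term]",
    "id: e: 0000415",
    "name: CS-bar-STRHY",
    "def: \"bar gene.\" [Thompson et al. (1987)]",
    "comment: Acetylates L-PPT.",
    "synonym: \"PAT\" EXACT []",
    "is_a: e: 0000188! CS-phosphinothricin N-acetyltransferase",
    "xref: BCH:14972",
    "xref: Trait:t\\:0000006 \"Glufosinate tolerance\"",
    "xref: Donor:Streptomyces_hygroscopicus",
    "xref: JRC:QL-FOO-01"
  )
  th <- read_obo(text = doc)
  t <- tidy(th)
  row <- t[t$term_id == "e:0000415", ]
  expect_identical(row$name, "CS-bar-STRHY")
  expect_identical(row$parent_id, "e:0000188")
  expect_identical(row$level, 3L)
  expect_identical(row$definition, "bar gene.")
  expect_identical(row$def_refs[[1]], "Thompson et al. (1987)")
  expect_identical(row$synonyms[[1]], "PAT")
  expect_identical(row$bch_id, 14972L)
  expect_identical(row$trait_refs[[1]], "t:0000006")
  expect_identical(row$trait_labels[[1]], "Glufosinate tolerance")
  expect_identical(row$donor, "Streptomyces hygroscopicus")
  expect_identical(row$other_xrefs[[1]], "JRC:QL-FOO-01")
  # the plain-colon trait form is accepted too
  th2 <- read_obo(text = sub("Trait:t\\\\:", "Trait:t:", doc, fixed = FALSE))
  expect_identical(tidy(th2)$trait_refs, t$trait_refs)
})

test_that("read_obo rejects broken documents", {
  expect_error(
    read_obo(text = c("[Term]", "id: e:0000001", "name: a",
                      "is_a: e:0000009")),
    "e:0000009"
  )
  expect_error(
    read_obo(text = c("[Term]", "id: e:0000001", "name: a", "",
                      "[Term]", "id: e:0000001", "name: b")),
    "duplicate term id"
  )
  expect_error(
    read_obo(text = c("[Term]", "name: no id here")),
    "no id"
  )
  expect_error(
    read_obo(text = c("[Term]", "id: e:0000001", "not a tag line")),
    "malformed tag line"
  )
})

test_that("a header-only document gives an empty thesaurus with metadata", {
  th <- read_obo(text = c("format-version: 1.2", "date: 01:01:2020 00:00"))
  expect_identical(nrow(tidy(th)), 0L)
  expect_identical(th$metadata[["date"]], "01:01:2020 00:00")
})

test_that("write_obo emits annotated is_a lines and is deterministic", {
  th <- build_example_thesaurus()
  lines <- write_obo(th)
  i <- which(lines == "id: e:0000415")
  block <- lines[i:(i + 10)]
  is_a <- grep("^is_a:", block, value = TRUE)
  expect_identical(
    is_a, "is_a: e:0000188 ! CS-phosphinothricin N-acetyltransferase"
  )
  # root-only thesaurus: header plus a single stanza
  root <- add_term(gmo_thesaurus(), "genetic element",
                   term_id = "e:0000000")
  out <- write_obo(root)
  expect_identical(sum(out == "[Term]"), 1L)
})

test_that("read/write round-trips random thesauri losslessly", {
  for (i in 1:20) {
    th <- generate_random_thesaurus(
      seed = 1000 + i,
      n_level2 = 3 + i %% 5,
      n_level3_per_branch = 1 + i %% 3,
      n_level4_rate = 0.3
    )
    lines <- write_obo(th)
    th2 <- read_obo(text = lines)
    expect_equal(th2, th, ignore_attr = FALSE)
    expect_identical(write_obo(th2), lines)
  }
})

test_that("typedef stanzas and unknown tags survive a round-trip", {
  doc <- c(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: e:0000000",
    "name: genetic element",
    "subset: core",
    "",
    "[Typedef]",
    "id: is_a",
    "name: is_a"
  )
  th <- read_obo(text = doc)
  expect_identical(tidy(th)$extra_tags[[1]], "subset: core")
  out <- write_obo(th)
  expect_true(all(c("[Typedef]", "id: is_a") %in% out))
  expect_identical(write_obo(read_obo(text = out)), out)
})

test_that("definitions with escapes survive serialization", {
  th <- add_term(
    gmo_thesaurus(), "genetic element", term_id = "e:0000000",
    definition = 'quoted "text" with \\ backslash',
    def_refs = c("Ref, with comma", "Plain ref"),
    synonyms = c('syn "quoted"')
  )
  th2 <- read_obo(text = write_obo(th))
  expect_identical(tidy(th2)$definition, tidy(th)$definition)
  expect_identical(tidy(th2)$def_refs, tidy(th)$def_refs)
  expect_identical(tidy(th2)$synonyms, tidy(th)$synonyms)
})

test_that("export_tsv flattens multi-valued fields", {
  tbl <- export_tsv(build_example_thesaurus())
  row <- tbl[tbl$name == "CS-bar-STRHY", ]
  expect_identical(row$term_id, "e:0000415")
  expect_identical(row$traits, "t:0000006")
  expect_identical(row$synonyms, "Bialaphos resistance|PAT")
})
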