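test_that("add_term computes levels from the parent and rejects breakage", {
  th <- tiny_thesaurus()
  th <- add_term(th, "CS-bar-STRHY", parent_id = "e:0000188",
                 term_id = "e:0000415")
  row <- tidy(th) |> dplyr::filter(term_id == "e:0000415")
  expect_identical(row$level, 3L)
  expect_identical(row$parent_id, "e:0000188")

  expect_error(
    add_term(th, "CS-other", parent_id = "e:0000188", term_id = "e:0000415"),
    "duplicate term id"
  )
  expect_error(
    add_term(th, "CS-self", parent_id = "e:0000999", term_id = "e:0000999"),
    "cycle"
  )
  expect_error(
    add_term(th, "CS-bar-STRHY", parent_id = "e:0000188"),
    "duplicate preferred name"
  )
  expect_error(
    add_term(th, "CS-x", parent_id = "e:0000777", term_id = "e:0000778"),
    "unknown parent"
  )
  expect_error(
    add_term(th, "second root", term_id = "e:0000900"),
    "already has a root"
  )
  # depth is capped at level_4
  th <- add_term(th, "CS-bar4-STRHY", parent_id = "e:0000415",
                 term_id = "e:0000500")
  expect_error(
    add_term(th, "CS-bar5-STRHY", parent_id = "e:0000500"),
    "inconsistent"
  )
  # the printed id form with a space is normalized
  th2 <- add_term(tiny_thesaurus(), "CS-pat-STRVR",
                  parent_id = "e: 0000188", term_id = "e: 0000206")
  expect_true("e:0000206" %in% tidy(th2)$term_id)
})

test_that("next_free_id fills gaps deterministically", {
  expect_identical(next_free_id(gmo_thesaurus()), "e:0000001")

  th <- gmo_thesaurus(tibble::tibble(
    term_id = c("e:0000001", "e:0000003"),
    name = c("a", "b"),
    parent_id = c(NA, "e:0000001")
  ))
  expect_identical(next_free_id(th), "e:0000002")

  # brute-force oracle over a contiguous block up to e:0000415
  n <- 415
  terms <- tibble::tibble(
    term_id = sprintf("e:%07d", 0:n),
    name = c("root", paste0("term ", 1:n)),
    parent_id = c(NA_character_, rep("e:0000000", n))
  )
  th <- gmo_thesaurus(terms)
  used <- 0:n
  oracle <- setdiff(1:9999999, used)[1]
  expect_identical(next_free_id(th), sprintf("e:%07d", oracle))
  expect_identical(next_free_id(th), "e:0000416")
})

test_that("the packaged fixture validates cleanly and is a tree", {
  th <- build_example_thesaurus()
  expect_identical(nrow(validate_thesaurus(th)), 0L)
  t <- tidy(th)
  expect_identical(sum(!is.na(t$parent_id)), nrow(t) - 1L)
  expect_identical(expand_term(th, "e:0000000"), sort(t$term_id))
})

test_that("validate_thesaurus reports the seeded violation classes", {
  th <- build_example_thesaurus()
  t <- tidy(th)
  mutate_and_rules <- function(f) {
    validate_thesaurus(gmo_thesaurus(f(t), metadata = th$metadata))$rule
  }
  # bad id pattern on a leaf
  expect_true("id_pattern" %in% mutate_and_rules(function(t) {
    t$term_id[t$term_id == "e:0000300"] <- "e:415"
    t
  }))
  # duplicated term id
  expect_true("duplicate_id" %in% mutate_and_rules(function(t) {
    dplyr::bind_rows(t, t[t$term_id == "e:0000300", ])
  }))
  # duplicated preferred name
  expect_true("duplicate_name" %in% mutate_and_rules(function(t) {
    t$name[t$term_id == "e:0000300"] <- "CS-bar-STRHY"
    t
  }))
  # dangling parent link
  expect_true("unknown_parent" %in% mutate_and_rules(function(t) {
    t$parent_id[t$term_id == "e:0000300"] <- "e:9999999"
    t
  }))
  # self-parent cycle
  expect_true("orphan_or_cycle" %in% mutate_and_rules(function(t) {
    t$parent_id[t$term_id == "e:0000300"] <- "e:0000300"
    t
  }))
  # level_1 name outside the controlled list
  expect_true("level1_name" %in% mutate_and_rules(function(t) {
    t$name[t$term_id == "e:0000007"] <- "promotor"
    t
  }))
  # terminator-prefixed name under the promoter branch
  expect_true("prefix_ancestor_mismatch" %in% mutate_and_rules(function(t) {
    t$name[t$term_id == "e:0000212"] <- "T-nosbis-RHIRD"
    t
  }))
  # level_3 name without a registry donor
  expect_true("name_grammar" %in% mutate_and_rules(function(t) {
    t$name[t$term_id == "e:0000300"] <- "CS-cry1Ab10"
    t
  }))
  # prefix missing from the registry
  expect_true("unknown_prefix" %in% mutate_and_rules(function(t) {
    t$name[t$term_id == "e:0000300"] <- "QQQ-cry1Ab10-BACTK"
    t
  }))
})

test_that("a sequence of successful add_term calls stays valid", {
  th <- tiny_thesaurus()
  th <- add_term(th, "CS-bar-STRHY", parent_id = "e:0000188")
  th <- add_term(th, "CS-pat-STRVR", parent_id = "e:0000188")
  th <- add_term(th, "P-nos-RHIRD", parent_id = "e:0000020")
  expect_identical(nrow(validate_thesaurus(th)), 0L)
})

test_that("glance summarizes term counts", {
  g <- glance(build_example_thesaurus())
  expect_identical(g$n_terms, 40L)
  expect_identical(g$n_level3, 15L)
  expect_identical(g$n_level4, 1L)
  expect_identical(g$n_bch_xrefs, 12L)
})
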