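fixture <- build_example_thesaurus()

test_that("predict_detection distinguishes detected, possible, not_detected", {
  gmos <- tibble::tribble(
    ~gmo_id,  ~element_id,
    "GMO-A",  "e:0000300",   # annotated with the cry1Ab10 variant
    "GMO-B",  "e:0000204",   # annotated with cry1Ac
    "GMO-C",  "e:0000203",   # annotated with the cry1Ab parent element
    "GMO-D",  NA_character_  # no annotations at all
  )
  methods <- tibble::tribble(
    ~method_id,     ~target_id,
    "M-cry1Ab",     "e:0000203",  # targets CS-cry1Ab-BACTU
    "M-cry1Ab10",   "e:0000300"   # targets the level_4 variant
  )
  m <- predict_detection(fixture, gmos, methods)
  call_of <- function(g, mm) {
    as.character(m$call[m$gmo_id == g & m$method_id == mm])
  }
  # a variant-annotated GMO is detected by the parent-element method
  expect_identical(call_of("GMO-A", "M-cry1Ab"), "detected")
  # a sibling element never contains the variant target
  expect_identical(call_of("GMO-B", "M-cry1Ab10"), "not_detected")
  # annotation broader than the target: presence unconfirmed
  expect_identical(call_of("GMO-C", "M-cry1Ab10"), "possible")
  # an unannotated GMO is not detected by anything
  expect_true(all(m$call[m$gmo_id == "GMO-D"] == "not_detected"))
  # every pair appears exactly once
  expect_identical(nrow(m), 8L)
  expect_identical(anyDuplicated(m[c("gmo_id", "method_id")]), 0L)

  # binary mode collapses possible
  mb <- predict_detection(fixture, gmos, methods, binary = TRUE)
  expect_identical(
    as.character(mb$call[mb$gmo_id == "GMO-C" & mb$method_id == "M-cry1Ab10"]),
    "not_detected"
  )
})

test_that("predict_detection validates its inputs", {
  gmos <- tibble::tibble(gmo_id = "G", element_id = "e:9999999")
  methods <- tibble::tibble(method_id = "M", target_id = "e:0000203")
  expect_error(predict_detection(fixture, gmos, methods), "unknown element")
  gmos$element_id <- "e:0000188"  # a level_2 term
  expect_error(predict_detection(fixture, gmos, methods), "level 3-4")
  gmos$element_id <- "e:0000415"
  methods$target_id <- "e:9999999"
  expect_error(predict_detection(fixture, gmos, methods), "unknown method")
})

test_that("coverage_report recounts the calls", {
  gmos <- tibble::tribble(
    ~gmo_id, ~element_id,
    "GMO-A", "e:0000300",
    "GMO-B", "e:0000204",
    "GMO-C", "e:0000203"
  )
  methods <- tibble::tibble(method_id = "M-cry1Ab", target_id = "e:0000203")
  rep <- coverage_report(predict_detection(fixture, gmos, methods))
  row <- rep$methods[rep$methods$method_id == "M-cry1Ab", ]
  expect_identical(row$detected, 2L)
  expect_identical(row$not_detected, 1L)
  expect_identical(
    rep$gmos$detecting_methods[rep$gmos$gmo_id == "GMO-A"], "M-cry1Ab"
  )
  # empty inputs give an empty report
  empty <- coverage_report(predict_detection(
    fixture,
    tibble::tibble(gmo_id = character(), element_id = character()),
    tibble::tibble(method_id = character(), target_id = character())
  ))
  expect_identical(nrow(empty$methods), 0L)
  expect_identical(nrow(empty$gmos), 0L)
  # all GMOs annotated with the target itself are all detected
  all_t <- tibble::tibble(gmo_id = c("G1", "G2"), element_id = "e:0000415")
  rep2 <- coverage_report(predict_detection(
    fixture, all_t,
    tibble::tibble(method_id = "M", target_id = "e:0000415")
  ))
  expect_identical(rep2$methods$detected, 2L)
})

test_that("predict_detection agrees with the brute-force oracle", {
  for (i in 1:15) {
    th <- generate_random_thesaurus(3000 + i, n_level2 = 4,
                                    n_level3_per_branch = 2,
                                    n_level4_rate = 0.4)
    ann <- generate_random_annotations(4000 + i, th, n_gmos = 8,
                                       n_methods = 5,
                                       annotation_rate = 0.5)
    m <- predict_detection(th, ann$gmos, ann$methods)
    t <- tidy(th)
    elements_of <- split(ann$gmos$element_id, ann$gmos$gmo_id)
    target_of <- stats::setNames(ann$methods$target_id, ann$methods$method_id)
    for (k in seq_len(nrow(m))) {
      els <- elements_of[[m$gmo_id[k]]]
      els <- els[!is.na(els)]
      expect_identical(
        as.character(m$call[k]),
        oracle_call(t, els, target_of[[m$method_id[k]]])
      )
    }
    # partition: each pair has exactly one call
    expect_identical(nrow(m),
                     length(elements_of) * nrow(ann$methods))
  }
})

test_that("moving a target to an ancestor never shrinks the detected set", {
  for (i in 1:10) {
    th <- generate_random_thesaurus(5000 + i, n_level2 = 4,
                                    n_level3_per_branch = 2,
                                    n_level4_rate = 0.4)
    ann <- generate_random_annotations(6000 + i, th, n_gmos = 8,
                                       n_methods = 4,
                                       annotation_rate = 0.7)
    t <- tidy(th)
    m <- predict_detection(th, ann$gmos, ann$methods)
    for (j in seq_len(nrow(ann$methods))) {
      anc <- oracle_ancestors(t, ann$methods$target_id[j])
      if (!length(anc)) next
      up <- ann$methods[j, ]
      up$target_id <- anc[1]
      m_up <- predict_detection(th, ann$gmos, up)
      det <- m$gmo_id[m$method_id == up$method_id & m$call == "detected"]
      det_up <- m_up$gmo_id[m_up$call == "detected"]
      expect_true(all(det %in% det_up))
    }
  }
})

test_that("detection matrices reshape and plot", {
  gmos <- tibble::tibble(gmo_id = "GMO-A", element_id = "e:0000300")
  methods <- tibble::tibble(method_id = "M1", target_id = "e:0000203")
  m <- predict_detection(fixture, gmos, methods)
  wide <- detection_wide(m)
  expect_identical(wide$M1, "D")
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})
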