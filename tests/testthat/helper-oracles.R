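# Independent brute-force oracles: closure by repeated edge expansion over
# the raw parent links, never via the package's child index.

oracle_expand <- function(terms, id) {
  out <- id
  repeat {
    nxt <- terms$term_id[!is.na(terms$parent_id) &
                           terms$parent_id %in% out &
                           !terms$term_id %in% out]
    if (!length(nxt)) break
    out <- c(out, nxt)
  }
  sort(out)
}

oracle_ancestors <- function(terms, id) {
  out <- character()
  cur <- terms$parent_id[terms$term_id == id]
  while (length(cur) == 1L && !is.na(cur)) {
    out <- c(out, cur)
    cur <- terms$parent_id[terms$term_id == cur]
  }
  out
}

oracle_call <- function(terms, elements, target) {
  if (any(elements %in% oracle_expand(terms, target))) {
    "detected"
  } else if (any(elements %in% oracle_ancestors(terms, target))) {
    "possible"
  } else {
    "not_detected"
  }
}

# a minimal valid thesaurus: root, two level_1 types, one branch each
tiny_thesaurus <- function() {
  th <- gmo_thesaurus()
  th <- add_term(th, "genetic element", term_id = "e:0000000")
  th <- add_term(th, "coding sequence", parent_id = "e:0000000",
                 term_id = "e:0000001")
  th <- add_term(th, "promoter", parent_id = "e:0000000",
                 term_id = "e:0000002")
  th <- add_term(th, "CS-phosphinothricin N-acetyltransferase",
                 parent_id = "e:0000001", term_id = "e:0000188")
  th <- add_term(th, "P-nopaline synthase", parent_id = "e:0000002",
                 term_id = "e:0000020")
  th
}
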