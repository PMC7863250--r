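Package: gmoget
Title: Controlled Vocabulary Tools for Genetic Elements in GMOs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building, validating, serializing and querying a
    mono-hierarchical controlled vocabulary (thesaurus) of genetic elements
    introduced or altered in genetically modified organisms (GMOs), in the
    style of the GMO-GET standard used by GMO registries and enforcement
    laboratories. Provides a formal grammar for element designations of the
    form XX-YYYY-ZZZZZ (element-type prefix, element abbreviation, donor
    organism code) with normalization rules and a linter, a lossless reader
    and writer for the OBO flat-file dialect used to exchange the
    vocabulary, hierarchy-aware queries (descendant expansion, synonym
    search, cross-database identifier resolution), and prediction of which
    GMOs an element-specific detection method can identify from element
    annotations alone.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
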