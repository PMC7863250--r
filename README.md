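# gmoget

Tools for the controlled vocabulary of genetic elements in genetically
modified organisms (GMOs).

## The problem

Enforcement laboratories, risk assessors and registry curators all
describe GMOs by the genetic elements inserted into (or, for genome-edited
organisms, altered in) their genomes — promoters, coding sequences,
terminators and so on. The major GMO databases use different, informal
vocabularies for those elements, which blocks automated data exchange and
makes it hard to answer the operational question "which GMOs can this
element-specific PCR assay detect?". The GMO genetic element thesaurus
(GMO-GET) standard addresses this with a mono-hierarchical controlled
vocabulary and a formal naming grammar; `gmoget` implements that standard
as a reusable toolkit for R.

The core pieces:

- **A five-level mono-hierarchy.** Every term has exactly one broader
  term via `is_a`, so the vocabulary is a single tree: level 0 is the
  root "genetic element", level 1 the twelve element types, level 2 the
  functional long names (e.g. `CS-phosphinothricin N-acetyltransferase`),
  level 3 the concrete element designations, and level 4 sequence
  variants of an element.
- **A name grammar.** Level 3–4 designations follow `XX-YYYY-ZZZZZ`:
  an element-type prefix (`CS`, `P`, `T`, ...), an element abbreviation
  with normalization rules (lowercase unless the common abbreviation is
  mixed-case, Greek letters spelled out, special characters replaced by
  `_`, UTR designators and embedded species abbreviations removed), and a
  donor-organism code (UniProt-style mnemonics, virus acronyms, or
  `SYNTH` for hybrid constructs). Modifier suffixes mark genome-edited
  (`_genome_edited`) and silencing (`_siRNAs`/`_siRNAas`/`_siRNAu`)
  elements.
- **OBO exchange.** The vocabulary is serialized in the OBO flat-file
  dialect; `read_obo()`/`write_obo()` round-trip it losslessly and
  byte-stably.
- **Hierarchy-aware querying.** `expand_term()` is the
  reflexive-transitive `is_a` closure, so a query with a level-2 term
  finds everything annotated with its narrower terms; `find_terms()`
  matches names/synonyms, `resolve_xref()` maps BCH, trait and donor
  identifiers.
- **Detection-matrix prediction.** Given GMO→element annotations and
  method→target assignments, `predict_detection()` calls each GMO × method
  pair `detected` (an annotated element lies in the closure of the
  target), `possible` (the annotation is a strict ancestor of a
  variant-specific target, so presence is unconfirmed) or `not_detected`.

## Worked example

```r
library(gmoget)
library(tibble)

th <- build_example_thesaurus()   # the packaged example thesaurus
glance(th)
#> # A tibble: 1 × 8
#>   n_terms n_level1 n_level2 n_level3 n_level4 n_synonyms n_bch_xrefs n_trait_xrefs
#>     <int>    <int>    <int>    <int>    <int>      <int>       <int>         <int>
#> 1      40       12       11       15        1         22          12             8

# lint a legacy designation: the embedded species abbreviation belongs
# in the donor segment
lint_name("CS-AtAHAS")
#> # A tibble: 1 × 5
#>   name      rule                 span  message                                  replacement
#> 1 CS-AtAHAS species_abbreviation At    embedded species abbreviation belongs...  CS-ahas-ARATH

# which GMOs does a cry1Ab-specific assay detect?
gmos <- tribble(~gmo_id, ~element_id,
  "GMO-A", "e:0000300",   # annotated with the cry1Ab10 sequence variant
  "GMO-B", "e:0000204",   # annotated with the sibling element cry1Ac
  "GMO-C", "e:0000203")   # annotated with the cry1Ab parent element
methods <- tribble(~method_id, ~target_id,
  "M-cry1Ab",   "e:0000203",  # targets CS-cry1Ab-BACTU
  "M-cry1Ab10", "e:0000300")  # targets the level-4 variant
predict_detection(th, gmos, methods)
#> # A tibble: 6 × 3
#>   gmo_id method_id  call
#> 1 GMO-A  M-cry1Ab   detected
#> 2 GMO-A  M-cry1Ab10 detected
#> 3 GMO-B  M-cry1Ab   not_detected
#> 4 GMO-B  M-cry1Ab10 not_detected
#> 5 GMO-C  M-cry1Ab   detected
#> 6 GMO-C  M-cry1Ab10 possible
```

A GMO annotated with the variant is detected by the parent-element method
(variants contain the parent's target sequence); a GMO annotated only
with the parent is merely `possible` for the variant-specific assay; the
sibling element `cry1Ac` is never confused with a `cry1Ab` target.
`coverage_report()` tallies the calls per method, `detection_wide()`
writes the D/P/N grid, and `autoplot()` draws it.

A command-line interface wraps the same functions
(`inst/scripts/gmoget`): `validate`, `lint-names`, `query`, `convert`,
`matrix`, `fixture`, with results on stdout and diagnostics on stderr:

```sh
Rscript inst/scripts/gmoget fixture --out fx.obo
Rscript inst/scripts/gmoget query fx.obo --xref BCH:14972
# e:0000415	CS-bar-STRHY
```

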