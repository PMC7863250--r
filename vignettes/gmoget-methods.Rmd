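---
title: "Designing and querying a genetic-element thesaurus for GMO detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and querying a genetic-element thesaurus for GMO detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmoget)
library(tibble)
```

## The model

`gmoget` implements a controlled vocabulary (thesaurus in the ISO 25964
sense) for the genetic elements introduced into conventional GMOs or
altered in genome-edited organisms. Three modelling commitments shape
everything else:

1. **Mono-hierarchy.** Each term has exactly one broader term via the
   single relation `is_a`, so the vocabulary is a tree, not a DAG. This
   is deliberate: a thesaurus with one preferred term per concept and one
   broader term per term keeps query expansion unambiguous (the
   expansion sets of siblings are provably disjoint) and keeps the data
   model simple enough for registry curators to maintain by hand. The
   cost is that an element with two equally natural parents must be
   filed under one of them; the other relation can only be recorded
   informally.

2. **Five levels.** Level 0 is the root concept "genetic element";
   level 1 is a closed list of twelve element types (coding sequence,
   promoter, terminator, intron, leader, enhancer, transit peptide,
   vector fragment, other regulatory elements, gene silencing elements,
   genomic sequence, unknown origin); level 2 groups elements by
   function under a long name (`CS-nopaline synthase`); level 3 holds
   the concrete element designations; level 4 holds sequence variants of
   a level-3 element. Variants matter operationally: a PCR assay
   designed against one variant may fail on another, which is exactly
   what the detection matrix's three-valued call captures.

3. **A formal name grammar at levels 3–4.** Designations follow
   `XX-YYYY-ZZZZZ`: element-type prefix, element abbreviation (stem),
   donor-organism code. Because stems may legally contain hyphens
   (`beta-gal`), parsing anchors on the *first* hyphen for the prefix
   and accepts the segment after the *last* hyphen as donor only when it
   is a key of the donor registry; anything else stays part of the stem.
   A naive three-way split would mis-parse legitimate published names.

## Term records and identifiers

Each term carries a preferred name, a definition with citations, a
free-text function note, synonyms (non-preferred names), at most one
parent, trait references into a separate trait vocabulary (modelled here
as opaque `t:NNNNNNN` identifiers), an optional integer BCH (Biosafety
Clearing-House) identifier, an optional donor-organism annotation, and
arbitrary further cross-references. Identifiers are `e:` plus exactly
seven digits; the printed variant with a space after the colon
(`e: 0000415`) is accepted on input and normalized, because
whitespace-free identifiers are required in OBO cross-reference fields.
Element (`e:`) and trait (`t:`) identifiers are treated as independent
namespaces; nothing in the exchanged files requires a shared counter.

## Normalization rules and their order

`normalize_stem()` applies the naming rules in a fixed order chosen so
the pipeline is idempotent and each rule sees the output of the previous
one:

1. strip 3′/5′ UTR designators (redundant with the `T-`/`P-` prefix);
2. strip a leading genus-species abbreviation (`At`, `Zm`, ...) *only*
   when it denotes the declared or inferred donor — never on
   capitalization alone, so stems like `bar` are untouched. The literal
   token `CP4` is always retained: it names an *Agrobacterium* strain
   with no donor mnemonic of its own, so `CS-CP4epsps-RHIRD` keeps it;
3. transliterate Greek letters to spelled-out names (`β` → `beta`),
   covering all 24 letters in both cases;
4. replace the special characters `.`, `/`, the acute accent and its
   typographic variants, and whitespace with `_`. This set is closed by
   design: other unusual Unicode punctuation raises a
   `nonstandard_character` diagnostic instead of being silently
   replaced, because the convention's own list is open-ended ("e.g.")
   and guessing risks destroying information;
5. lowercase, then restore canonical mixed-case spellings from a
   packaged override list seeded with the published designations
   (`cry1Ab`, `CP4epsps`, `rbcS_E9`, `35S`, ...), longest match first.

`lint_name()` attributes each difference between the input and its
canonical form to the rule that caused it, one diagnostic per rule, each
carrying the offending span and the full canonical replacement. When a
species abbreviation is stripped, the lowercasing of the remaining stem
is part of the same legacy convention (CamelCase genus prefix), so it is
folded into that single diagnostic rather than reported twice.

Donor inference: when a designation has no donor segment, the donor can
be inferred from a leading species abbreviation via an explicit lookup
table (`CS-AtAHAS` → donor `ARATH`). The table is data, not heuristics,
and only abbreviations listed there ever trigger stripping or inference.

## Serialization

The OBO 1.2 flat-file dialect is the exchange format. Writing is
deterministic — stanzas sorted by term id, tags in a fixed order — so a
write → read → write cycle is byte-identical, which makes diffs of
vocabulary releases meaningful. Reading is liberal where the printed
sources are inconsistent: trait cross-references are accepted with either
an escaped or a plain colon (and written escaped, `Trait:t\:0000006`),
donor targets with spaces or underscores (written with underscores,
since spaces are illegal in OBO xref targets). Definitions are stored as
quoted text plus a bracketed citation list with commas escaped; the
function note is a single `comment:` line because OBO comments have no
citation syntax. Synonym scope is not specified by the convention, so
all synonyms are written `EXACT`. `[Typedef]` stanzas and unknown tags
are preserved verbatim.

## Query expansion and the detection matrix

`expand_term()` returns the reflexive-transitive closure of `is_a`
children. The detection matrix builds directly on it: a method whose
assay targets element *t* detects a GMO iff the GMO is annotated with
any element in `expand(t)` — a narrower variant contains the target
sequence. If no such element exists but the GMO is annotated with a
strict *ancestor* of *t*, the GMO may or may not carry the targeted
variant, and the call is `possible`. A binary output would have to
resolve that case silently in one direction and would either overclaim
detections or discard real screening candidates; the three-valued call
keeps the ambiguity explicit, and `binary = TRUE` collapses `possible`
to `not_detected` for consumers that need a hard matrix. A level-4
annotation against a method targeting a *different* level-3 parent under
the same level-2 grandparent is `not_detected` — closure membership, not
family resemblance, decides.

Method targets at level 2 are allowed (screening assays against broadly
shared elements such as the 35S promoter are standard practice); the
semantics are unchanged.

## The packaged fixture and the random generator

`build_example_thesaurus()` deterministically reconstructs the published
worked-example terms: 40 terms, 16 level 3–4 designations, 12 BCH
identifiers, with definitions and citations stored verbatim as data.
Printed artifacts (a trait reference that contradicts the term's own
description, a designation that violates the grammar, one spelling
error) are reproduced, not corrected, and documented in
`inst/extdata/fixture-NOTES.md`; the grammar-violating printed name is
kept as a synonym of its conformant canonicalization. The builder's
output is byte-identical to the checked-in `gmo-get-fixture.obo`.

`generate_random_thesaurus()` emulates the *structure* of real
vocabularies for property tests: the full level-1 layer, branches over
the nine single-prefix element types, grammar-conformant level-3 names
with random lowercase stems and registry donors, occasional
genome-edited modifiers and level-4 variants, plus randomized synonyms,
BCH ids, traits, definitions and citations to exercise serialization.
Default sizes (6 level-2 branches, 3 level-3 terms each, level-4 rate
0.2) give thesauri of roughly 35–45 terms — the scale of a curated
branch — and the property tests vary the sizes up to the 100-term cap.
What the generator does *not* emulate: biologically meaningful
abbreviations, shared stems across element types, cross-branch trait
structure, and the legacy misspellings real curation inherits. Passing
the round-trip and closure properties on generated data therefore
demonstrates correctness of the mechanics, not robustness to every
historical naming accident; the fixture corpus covers the published
accidents explicitly.

`generate_random_annotations()` draws per-GMO element counts as
Binomial(4, `annotation_rate`) over level 3–4 terms (four is a typical
insert's worth of distinct annotated elements) and method targets
uniformly over levels 2–4.

## Numerical and procedural choices

- Sibling order is serialized sorted by term id, making writes
  reproducible regardless of insertion order.
- `next_free_id()` fills identifier gaps (smallest unused id first) so
  reconstructed vocabularies reuse retired numbers deterministically.
- Validation returns violations as data (a tibble of rule, term,
  message), never as conditions, so a curator can see *all* problems at
  once; the violation list is exhaustively ordered by rule class then
  term id.
- Name/synonym search is exact and case-insensitive; substring search
  exists only behind the CLI `--contains` flag, keeping the default
  semantics safe for automated joins.
- BCH identifiers are not assumed unique across terms; resolution
  returns all carriers (sorted) and the CLI warns on multiplicity.
- Property-test problem sizes — 200 serialization/closure thesauri of at
  most 100 terms, 100 detection-matrix instances of 6 GMOs × 4
  methods — were chosen as the package's own test scale: large enough to
  hit every structural configuration the generator can produce, small
  enough that the whole suite runs comfortably on one CPU.

## Known limitations

- No DAG support: an element genuinely belonging to two branches must be
  filed once.
- The trait vocabulary is modelled as opaque identifiers; trait
  semantics (e.g. the herbicide-tolerance hierarchy) live elsewhere.
- No sequence-level reasoning: the detection matrix works from
  annotations and hierarchy only, not from amplicon or primer sequences,
  so it predicts *potential* detectability, not assay performance.
- Donor-code matching is case-sensitive and registry-authoritative;
  virus acronym casing follows whatever the registry records.
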