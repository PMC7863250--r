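# Notes on the packaged fixture thesaurus

The fixture (`gmo-get-fixture.obo`, regenerated byte-identically by
`build_example_thesaurus()`) transcribes the published worked-example terms of
the GMO genetic element thesaurus, including their free-text definition and
function cells with citations. Transcription choices and apparent artifacts
in the printed source are recorded here rather than silently corrected:

- `CS-ppo_genome_edited-AGABB` is listed with trait `t:0000029`
  ("Glufosinate tolerance") in the printed table even though the term
  describes enzymatic browning of mushrooms. The fixture reproduces the
  printed value.
- The printed attribute table gives `CS-bar-STRHY` trait
  `Trait:t:0000006` ("Herbicide tolerance > Glufosinate tolerance") while
  the examples table lists `t:0000029` for the same term. The fixture
  follows the attribute table (`t:0000006`); `CS-pat-STRVR` keeps
  `t:0000029`.
- The printed designation "P-34S FMV" does not conform to the
  XX-YYYY-ZZZZZ grammar; the fixture records the conformant `P-34S-FMV`
  as preferred name and keeps the printed form as a synonym.
- The printed level_2 cell "CS- Polyphenol oxidase" (stray space, capital
  P) is recorded as `CS-polyphenol oxidase`.
- The level_4 variant `CS-cry1Ab10-BACTK` appears in the printed table
  with no attributes of its own; the fixture records it bare under
  `CS-cry1Ab-BACTU`.
- "rinulose-1,5-bisphosphate carboxylase" in the `T-rbcS_E9-PEA`
  definition is the printed spelling (sic, for ribulose).
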