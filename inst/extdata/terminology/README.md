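# Terminology tables (synthetic subset)

One tab-separated file per code system (`code`, `display`, `parents`;
`parents` is a comma-separated list of parent codes encoding the is-a
hierarchy). The file name gives the system id, with `_` standing for `-`
(`SNOMED_CT.tsv` loads as `SNOMED-CT`).

These tables are a **curated, non-normative reconstruction**: only the small
set of concepts required by the shipped stroke guideline content is present,
and while codes follow the style of their respective terminologies, most
were assigned here for the synthetic experiment and must not be treated as
authoritative SNOMED CT / ICD-10 / ATC content. ICD-10 code nesting (e.g.
`G83.8` under `G83`) is expressed through explicit parent links, not through
string-prefix logic, so all systems share one subsumption semantics.
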