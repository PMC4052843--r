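Package: strokecds
Title: Archetype-Based Rule Engine for Retrospective Stroke Guideline
    Compliance Auditing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A declarative when/then rule engine over an archetype-styled
    clinical data model, shipped with executable acute-stroke guideline
    content: thrombolysis contraindication screening, National Institutes of
    Health Stroke Scale (NIHSS) score derivation, and European stroke-care
    compliance criteria. Patient cases are typed, path-addressable entry
    collections serialized in a key = <value> text dialect; rules bind
    guideline-local codes to archetype element paths and to SNOMED CT, ICD-10
    and ATC terminology groups with is-a subsumption. Includes a seeded
    synthetic acute-stroke cohort generator, an engine-independent brute-force
    compliance oracle, and audit reports with per-criterion and per-case
    verdicts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Roxygen: list(markdown = TRUE)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
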