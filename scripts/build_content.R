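#!/usr/bin/env Rscript
# Regenerates the shipped content files under inst/extdata from the package's
# code-defined guidelines and schemas. Run from the repository root after
# changing the content builders; the committed files are these exports.

suppressMessages(devtools::load_all(".", quiet = TRUE))

dir.create("inst/extdata/guidelines", recursive = TRUE, showWarnings = FALSE)
serialize_guideline(build_thrombolysis_guideline(),
                    "inst/extdata/guidelines/thrombolysis_contraindications.gdl")
serialize_guideline(build_nihss_guideline(),
                    "inst/extdata/guidelines/nihss_score.gdl")
serialize_guideline(build_euro_criteria_guideline(),
                    "inst/extdata/guidelines/euro_compliance_criteria.gdl")

save_schema_registry(stroke_schema_registry(), "inst/extdata/stroke_schemas.yaml")

# one example case file in each format
case <- generate_case("clean", 20140301, case_id = "example_clean")
dir.create("inst/extdata/cases", recursive = TRUE, showWarnings = FALSE)
write_case(case, "inst/extdata/cases/example_clean.case.dadl")
write_case_json(case, "inst/extdata/cases/example_clean.case.json")

cat("content written\n")
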