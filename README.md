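# strokecds

Retrospective guideline-compliance auditing for acute stroke care, built on
a declarative when/then rule engine over an archetype-styled clinical data
model.

## The problem

After an acute stroke admission, did care follow the guideline? Was
thrombolysis (clot-dissolving treatment) given to a patient who had a
contraindication — a recent lumbar puncture, a blood glucose below
3 mmol/L, an NIHSS score above 25? Was body temperature monitored in the
first 72 hours, and was low oxygen saturation acted on? Answering these
questions from coded EHR data is the job of computer-interpretable
guidelines. This package implements the whole experiment as a library:

* **Data model** — patient cases are sets of timestamped, archetype-typed
  entries (OBSERVATION / EVALUATION / INSTRUCTION / ACTION) whose elements
  are path-addressable typed values (`DV_QUANTITY`, `DV_CODED_TEXT`,
  `DV_DATE_TIME`, ...), validated against a registry of archetype schemas
  and serialized in a dADL-style `key = <value>` text dialect (plus an
  equivalent JSON form).
* **Rule language** — guidelines bind local codes (`$gt0008`) to archetype
  elements and write logic as `when`/`then` rules:
  `when = "$gt0008>25"`, `then = "$gt0016=true"`, with terminology
  subsumption (`$gt0003 is_a local::gt0102|stroke|`) resolved against
  SNOMED CT / ICD-10 / ATC tables, and datetime arithmetic
  (`$gt0004+PT4H30M<currentDateTime`) for look-back windows.
* **Engine** — forward chaining to a fixpoint under three-valued logic:
  a condition touching absent data is *unknown*, and a criterion that can
  be neither confirmed nor excluded is reported **indeterminate** rather
  than silently compliant.
* **Shipped content** — 16 archetype schemas, a terminology subset, and
  three guidelines: 14 thrombolysis contraindications (of a 19-item list;
  5 are too vague to formalise and are catalogued but never evaluated),
  NIHSS total-score derivation (57 item-mapping rules plus one summation
  rule), and 6 rules sampled from European stroke-management
  recommendations.
* **Cohort + oracle** — a seeded generator of synthetic acute-stroke cases
  (default: 49, cycling 30 scenario profiles) and an engine-free
  brute-force oracle that re-derives every criterion directly from the
  entries, standing in for manual chart review.

## A worked example

```r
library(strokecds)

case <- generate_case("glucose_low", seed = 42)
case
#> <patient case> glucose_low: 12 entries, reference 2014-11-30T22:29:23Z

verdicts <- engine_verdicts(case)
subset(as.data.frame(verdicts), status != "not_triggered")
#>                   criterion_id    status
#> 4         glucose_out_of_range triggered
#> 16 euro_thrombolysis_indicated triggered
#> 17        euro_temp_monitoring triggered
```

The hypoglycaemia scenario trips exactly one contraindication
(`glucose_out_of_range`: glucose below 3 mmol/L); the two `euro_*` rows are
*compliance* criteria, so `triggered` there is good news — thrombolysis was
indicated (deficit within 4.5 h of onset) and temperature was monitored
inside the 72 h window. A full audit aggregates a cohort:

```r
report <- audit(generate_cohort(49))
report
#> <compliance report> 49 cases, 4 non-compliant (thrombolysis despite contraindication)
#> # A tibble: 19 × 4
#>    criterion_id                         triggered not_triggered indeterminate
#>  1 bleeding_disorder_or_anticoagulation         4            45             0
#>  2 ct_haemorrhage                               2            47             0
#>  ...
#> 15 onset_over_4_5h                              6            43             0

glance(report)   # one-row summary; tidy(report) gives the long verdict table
autoplot(report) # stacked bars of verdicts per criterion
```

Four cases received a thrombolytic despite a triggered contraindication —
the audit's headline non-compliance count. `audit_with_oracle()` re-derives
every verdict with the brute-force oracle and confirms a 49/49 per-case
match with the engine.

A thin CLI wraps the same functions
(`exec/strokecds generate|check|validate`); `check --selftest` exits
non-zero if engine and oracle ever disagree.

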