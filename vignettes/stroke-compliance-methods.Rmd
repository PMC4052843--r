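---
title: "Methods: rule semantics, content and validation of the stroke compliance audit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule semantics, content and validation of the stroke compliance audit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokecds)
```

This vignette is the package's own account of what it computes and why the
design is the way it is. The package audits acute-stroke care records
retrospectively: given a patient case — a set of timestamped, typed,
archetype-bound entries — it decides, per guideline criterion, whether the
criterion was *triggered*, *not triggered*, or cannot be decided
(*indeterminate*), and aggregates cohort statistics including an overall
non-compliance count (a thrombolytic administered despite a triggered
contraindication).

## The data model

Entries follow the openEHR care-entry typology (OBSERVATION, EVALUATION,
INSTRUCTION, ACTION). Each entry maps archetype-internal paths such as
`/data[at0001]/items[at0002.1]` to one typed value: a count, a quantity
with a unit, a boolean, text, terminology-coded text, a timestamp or a
duration. An archetype schema fixes, per path, the value kind, the unit
where the kind is a quantity, and the allowed local codes where the kind is
coded. Sixteen schemas ship with the package; fourteen are modelled on
reusable international archetypes and two were purpose-built here: an NIHSS
observation and a thrombolysis-contraindications evaluation holding one
boolean element per representable criterion. The exact element paths and
at-codes of the two purpose-built schemas are this package's own
assignments (reconstructions, not byte-identical copies of any published
archetype); the same holds for the paths chosen for the problem/diagnosis
extension (a `Confidence` coded element with options *Suspicion* and
*Certainty*, and a full-timestamp `Date of initial onset`).

Three conventions are enforced throughout rather than configured:

* **Time.** All timestamps are ISO 8601 with an explicit zone, normalised
  to UTC and compared at second resolution. Durations are ISO 8601 periods
  restricted to weeks/days/hours/minutes/seconds; calendar months are
  rejected because their length depends on the anchor date and every
  interval in the shipped content is a fixed span.
* **Units.** Units are fixed per element by schema (mmol/l, mmHg, %, °C).
  A value in any other unit is a validation error; nothing is converted.
* **Multiplicity.** A case may hold any number of entries per archetype
  and `get_value()` is list-valued, because history screening ("any prior
  event in the window") must scan all of them.

Cases serialize to a small `key = <value>` text dialect in the style of
openEHR's dADL/ODIN, with each element value a type-tagged block
(`(DV_QUANTITY) <magnitude = <2.9> units = <"mmol/l">>`), and equivalently
to JSON; the JSON form is normative and both round-trip exactly. The
schema registry itself can be exported to and reloaded from a YAML config
file; the copy under `inst/extdata/stroke_schemas.yaml` is that export, and
the code-defined schemas are the single source of truth.

## The rule dialect and its semantics

A guideline has three parts: *bindings* assigning guideline-local codes
(`gt0008`) to archetype elements, marked `input` or `output`; *rules*, each
a `when` list (implicit conjunction) and a `then` list of assignments; and
*term groups*, named code sets possibly bound in several terminologies at
once (a "stroke" group holding both ICD-10 `I64` and SNOMED CT
`230690007`). Because no complete grammar for this kind of expression
dialect is standardised, the operator set and precedence here are package
decisions, documented with the parser: `||` loosest, then `&&`, `!`,
comparison/`is_a`, additive `+`/`-`, primary. Equality in conditions is
`==`; a bare `=` is assignment and is a parse error in when-position.
Numeric literals carry no unit — the unit comes from the bound element's
schema, and a mismatch is a validation error.

Two deliberate grammar extensions matter:

* Additive terms apply not only as `DateTime ± Duration` (the canonical
  onset-window form `$gt0004+PT4H30M<currentDateTime`) but also between
  numeric terms. The NIHSS total cannot be derived otherwise: the
  summation rule assigns `$gt2100=$gt2001+...+$gt2015`. An assignment
  whose right-hand side is still unknown simply does not apply yet, which
  is what stratifies item rules before the sum.
* `exists($gtXXXX)` probes whether a value is present — for an output
  binding, whether the working memory already holds it. The shipped
  set-false rules are guarded with `!exists(...)` so they only decide a
  flag that no set-true rule has raised.

**Evaluation.** The engine computes, per rule, the candidate tuples: the
cartesian product of the case's entries over the archetypes the rule's
input bindings touch (a rule joining diagnoses and procedures on a case
with 2 × 3 entries has 6 tuples). A rule fires if *any* tuple satisfies
all conditions — existential instance binding, chosen because
contraindication screening asks "does any prior event qualify". Conditions
are three-valued (Kleene): a comparison or `is_a` touching an absent value
is unknown, `FALSE && unknown` is `FALSE`, `TRUE && unknown` is unknown,
and a rule fires only on definite truth. Firing applies the assignments to
a working memory of output values; evaluation repeats, higher priority
first then declaration order, until a full pass changes nothing. A cap of
(number of rules + 1) passes turns a genuinely cyclic rule set into an
error rather than a hang. Re-assigning an identical value does not count
as a change, which is what makes the fixpoint detection sound.

After the fixpoint, an output element that was never assigned is
classified: if every rule governing it had at least one tuple and every
evaluation was definite false, the element is *determinately unset*
(reported as not triggered); otherwise it is *indeterminate*. This is the
load-bearing choice for auditing: absent data (no NIHSS recorded, no
glucose measured) must never read as "no contraindication". The shipped
criterion rules therefore come in pairs — an unguarded set-true rule
(priority 10) and a guarded set-false rule (priority 1) whose conditions
negate the qualifying conditions tuple-wise. With this stratification the
fixpoint is independent of declaration order, which the test suite checks
by permuting rules.

## Terminology

Code systems are concept tables with parent links forming a DAG;
subsumption (`is_a`) is reflexive-transitive reachability, checked against
a brute-force graph search on random DAGs in the tests. ICD-10 nesting
(`G83.8` under `G83`) is encoded as explicit parent links, not string
prefixes, so all systems share one semantics. Only a handful of codes are
fixed by the source material; the rest of the shipped tables are a curated,
clearly non-normative reconstruction (see
`inst/extdata/terminology/README.md`) sufficient to express the criteria —
the original 51-binding table is not reproducible and is not claimed.

One deviation from an earlier sketch of the content deserves a note: the
"anticoagulation treatment" group is bound to the ATC subgroups `B01AA`
(vitamin K antagonists), `B01AB` (heparins) and `B01AF` (direct factor Xa
inhibitors) rather than to all of `B01A`, because `B01A` also contains the
fibrinolytics (`B01AD`, including alteplase — the thrombolytic itself) and
antiplatelet agents; binding the whole subtree would have flagged every
treated patient as anticoagulated.

## The shipped criteria

Fourteen of the nineteen listed thrombolysis contraindications are
representable and each owns one boolean output flag; the five resting on
vague wording ("unclear symptoms", a blood-pressure rule without a stated
interval between boluses, "recent" severe haemorrhage, ">30% of the middle
cerebral artery", symptom recovery within 30 minutes) are catalogued with
`represented = FALSE` and never evaluated. Every threshold is strict
exactly as phrased: *higher than* 25 means 26 triggers and 25 does not;
*lower than* 3 mmol/L means 2.999 triggers and 3.0 does not; *more than*
4.5 hours, *below* 95%, *exceed* 37.5 °C, all likewise.

Look-back windows are fixed spans — last week = 168 h, last month =
30 days, last three months = 90 days — because calendar-month arithmetic is
ambiguous and fixed spans are testable. One refinement was forced by the
data model: the three-month rule names *stroke* among the qualifying
events, and the index stroke being treated is itself always within the
window. Diagnosis-based stroke history therefore only counts events more
than 24 h before the decision instant; procedure look-backs use the full
window (a lumbar puncture two hours ago is a real contraindication). This
is the package's operationalisation of "prior stroke"; a manual reviewer
would make the same exclusion implicitly.

The NIHSS content uses the standard 15-item instrument (total 0–42):
57 rules map each item's coded answer to its integer contribution
(one rule per answer level) and one rule sums the contributions — 58 rules.
The European-criteria file has 6 rules: two disjunct MRI-justification
rules, thrombolysis indication (ischaemic deficit and within 4.5 h of
onset), temperature monitoring and a pyrexia alert over the first 72 h, and
the oxygen rule that, below 95% SpO2, writes the oxygen code and the nasal
cannula delivery code (`at0006`) into the gas-administration outputs. The
thrombolysis file decomposes into 33 rules (the paired true/false rules are
a consequence of three-valued reporting); no claim is made that this
decomposition matches any particular historical rule count, and it is
documented per criterion in the file itself.

Two European criteria get an explicit audit-level mapping. Temperature
monitoring is a *presence* criterion: at least one temperature observation
inside the 72 h post-onset window. If the case has a stroke diagnosis with
a known onset but no qualifying observation, the verdict is "not
triggered" (monitoring did not happen) rather than indeterminate — absence
of monitoring is exactly the finding; only a missing onset anchor makes it
indeterminate. No sampling-frequency requirement is imposed. Oxygen
compliance, as distinct from the engine's recommendation output, is
operationalised as: if any SpO2 reading below 95% exists, a
gas-administration entry with the oxygen code at or after that reading
should exist, with the grace window defaulting to the decision instant.

## The synthetic cohort

The generator emulates the experiment's study conditions: 49 mock
acute-stroke admissions (the default size), each anchored at a thrombolysis
decision instant, cycling through 30 scenario profiles so that every
representable criterion is triggered by at least one case and untriggered
by at least one. Ranges are clinically plausible rather than fitted to any
real distribution: onset 0.8–4 h before the decision (5–10 h in the
late-presentation profile), glucose 4.5–7.5 mmol/L normally and 2–2.8 /
22.3–25 in the out-of-range profiles, SpO2 96–99.5% vs 87–93%, NIHSS item
levels drawn low (high profile: near-maximal), historic events 1–200 days
back. Every case carries a complete baseline record — index stroke
diagnosis with onset and a benign chronic diagnosis, NIHSS, glucose, blood
pressure, temperature series, oximetry, examination, CT imaging, a
medication, a procedure and an intravenous fluid — because the guarded
set-false rules need data to *exclude* criteria; profiles then perturb
single features, including missing-data profiles (no NIHSS, no glucose, no
temperature series) that exercise the indeterminate path.

Determinism: each case draws from a sub-seed derived from
`(master_seed, index)`, so any case regenerates independently and the
default cohort is byte-identical across runs. What the generator does
*not* emulate: free-text notes, coding errors and terminology variance
beyond the shipped subset, longitudinal multi-admission records, and
realistic covariance between vitals. Passing tests therefore show the
engine and content are internally coherent and match an independent
re-implementation on structured, schema-valid data — not that the content
would perform identically on messy production EHR extracts.

## Validation

The oracle (`oracle_check()`) re-implements every criterion straight over
the entries: no rule files, no parser, no working memory, and even
subsumption is a locally written ancestor walk. It mirrors the engine's
three-valued, existential semantics per criterion in plain code, playing
the role manual chart review plays for a deployed system. The headline
test generates the default cohort and requires the entire per-case verdict
vector to match for all 49 cases; a fuzz test repeats this over 1000
generated cases across all profiles and seeds. Decision boundaries are
additionally recovered black-box (scans over integers, bisection to
0.001–0.01 resolution on single-feature cases) and compared with the
published thresholds.

Problem sizes used by the shipped test suite and acceptance script: the
49-case default cohort for concordance, 1000 fuzzed cases for oracle
equivalence, 1000 random item vectors for NIHSS conservation, DAGs up to 50
nodes for subsumption, and 300 random strings for parser totality. These
sizes were chosen as comfortably beyond the scale of the experiment being
reproduced while keeping the whole suite in the minutes range.

## Known limitations

* The dialect is GDL-*style*, not a compatible implementation of any
  published GDL version; files from other tools will not parse.
* Five of the nineteen contraindications are catalogued but not
  executable, by design.
* The terminology subset is synthetic beyond its anchor codes; real
  deployments would bind against full terminology services.
* The engine is a batch, retrospective evaluator; no point-of-care
  alerting loop, event scheduling or query-language-backed retrieval.
* Unit conversion is intentionally absent: a glucose in mg/dL is rejected,
  not converted.
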