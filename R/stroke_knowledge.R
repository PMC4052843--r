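#' Shipped acute-stroke knowledge content
#'
#' The package ships executable guideline content for acute stroke care:
#'
#' * sixteen archetype schemas (fourteen modelled on reusable international
#'   archetypes, two purpose-built: an NIHSS observation and a thrombolysis
#'   contraindications evaluation consisting of boolean flags);
#' * a terminology subset for SNOMED CT, ICD-10 and ATC with is-a hierarchy
#'   links (a curated reconstruction; see the terminology data directory);
#' * three guidelines: thrombolysis contraindication screening (14 criteria),
#'   NIHSS total-score derivation, and a sample of European stroke-care
#'   compliance criteria.
#'
#' The five contraindications from the source list that rest on vague
#' wording (e.g. "unclear symptoms", thresholds without a stated time
#' interval) are catalogued with `represented = FALSE` and are never
#' evaluated.
#'
#' @name stroke-knowledge
NULL

# Archetype ids and element paths used by the stroke content.
sk <- list(
  glucose = "openEHR-EHR-OBSERVATION.lab_test-blood_glucose",
  bp = "openEHR-EHR-OBSERVATION.blood_pressure",
  temp = "openEHR-EHR-OBSERVATION.body_temperature",
  oximetry = "openEHR-EHR-OBSERVATION.indirect_oximetry",
  exam = "openEHR-EHR-OBSERVATION.exam",
  nihss = "openEHR-EHR-OBSERVATION.nihss",
  diagnosis = "openEHR-EHR-EVALUATION.problem_diagnosis",
  contra = "openEHR-EHR-EVALUATION.thrombolysis_contraindications",
  alert = "openEHR-EHR-EVALUATION.alert",
  imaging = "openEHR-EHR-INSTRUCTION.imaging",
  medication = "openEHR-EHR-INSTRUCTION.medication",
  procedure = "openEHR-EHR-ACTION.procedure",
  ivf = "openEHR-EHR-ACTION.intravenous_fluid_administration",
  gas = "openEHR-EHR-ITEM_TREE.gas_administration",
  tree_imaging = "openEHR-EHR-ITEM_TREE.imaging",
  tree_medication = "openEHR-EHR-ITEM_TREE.medication",

  p_glucose = "/data[at0001]/items[at0078.1]",
  p_sys = "/data[at0001]/items[at0004]",
  p_dia = "/data[at0001]/items[at0005]",
  p_temp = "/data[at0002]/items[at0004]",
  p_temp_time = "/data[at0002]/items[at0021]",
  p_spo2 = "/data[at0001]/items[at0006]",
  p_exam = "/data[at0001]/items[at0003]",
  p_diag = "/data[at0001]/items[at0002.1]",
  p_onset = "/data[at0001]/items[at0003]",
  p_confidence = "/data[at0001]/items[at0100]",
  p_nihss_total = "/data[at0001]/items[at0090]",
  p_img_findings = "/activities[at0001]/description[at0002]/items[at0003]",
  p_img_site = "/activities[at0001]/description[at0002]/items[at0007]",
  p_proc = "/description[at0001]/items[at0002]",
  p_proc_time = "/description[at0001]/items[at0049]",
  p_med = "/activities[at0001]/description[at0002]/items[at0001]",
  p_med_start = "/activities[at0001]/description[at0002]/items[at0018]",
  p_fluid = "/description[at0001]/items[at0004]",
  p_fluid_time = "/description[at0001]/items[at0005]",
  p_gas = "/items[at0001]",
  p_gas_means = "/items[at0002]",
  p_gas_time = "/items[at0003]"
)

nihss_item_path <- function(k) sprintf("/data[at0001]/items[at%04d]", 100 + k)
nihss_contrib_path <- function(k) sprintf("/data[at0001]/items[at%04d]", 300 + k)
nihss_level_code <- function(k, l) sprintf("at2%02d%d", k, l)

#' The NIHSS instrument shipped with the package
#'
#' The standard 15-item form: each item is answered on an ordinal scale and
#' contributes its level to the total, which ranges 0-42.
#'
#' @return Tibble with columns `item`, `name`, `n_levels`, `max_score`,
#'   `path`.
#' @export
nihss_items <- function() {
  tibble::tibble(
    item = 1:15,
    name = c("Level of consciousness", "LOC questions", "LOC commands",
             "Best gaze", "Visual fields", "Facial palsy",
             "Motor arm left", "Motor arm right",
             "Motor leg left", "Motor leg right",
             "Limb ataxia", "Sensory", "Best language", "Dysarthria",
             "Extinction and inattention"),
    n_levels = c(4L, 3L, 3L, 3L, 4L, 4L, 5L, 5L, 5L, 5L, 3L, 3L, 4L, 3L, 3L),
    max_score = n_levels - 1L,
    path = vapply(1:15, nihss_item_path, character(1))
  )
}

# The sixteen schemas, built in code (the single source of truth); the
# shipped YAML registry file is their export, see save_schema_registry().
stroke_schemas <- function() {
  cel <- function() element_def("coded_text")
  qty <- function(unit) element_def("quantity", unit = unit)
  items <- nihss_items()
  nihss_elements <- list()
  for (k in items$item) {
    codes <- stats::setNames(paste0(items$name[k], ", score ",
                                    0:(items$n_levels[k] - 1L)),
                             nihss_level_code(k, 0:(items$n_levels[k] - 1L)))
    nihss_elements[[items$path[k]]] <- element_def("coded_text", codes = codes)
  }
  for (k in items$item) {
    nihss_elements[[nihss_contrib_path(k)]] <- element_def("count")
  }
  nihss_elements[[sk$p_nihss_total]] <- element_def("count")

  contra_elements <- list()
  for (i in 1:14) {
    contra_elements[[sprintf("/data[at0001]/items[at%04d]", i + 1L)]] <-
      element_def("boolean")
  }

  list(
    archetype_schema(sk$glucose, "OBSERVATION",
      stats::setNames(list(qty("mmol/l")), sk$p_glucose)),
    archetype_schema(sk$bp, "OBSERVATION",
      stats::setNames(list(qty("mmHg"), qty("mmHg")), c(sk$p_sys, sk$p_dia))),
    archetype_schema(sk$temp, "OBSERVATION",
      stats::setNames(list(qty("\u00b0C"), element_def("date_time")),
                      c(sk$p_temp, sk$p_temp_time))),
    archetype_schema(sk$oximetry, "OBSERVATION",
      stats::setNames(list(qty("%")), sk$p_spo2)),
    archetype_schema(sk$exam, "OBSERVATION",
      stats::setNames(list(cel()), sk$p_exam)),
    archetype_schema(sk$nihss, "OBSERVATION", nihss_elements),
    archetype_schema(sk$diagnosis, "EVALUATION",
      stats::setNames(list(cel(), element_def("date_time"),
                           element_def("coded_text",
                                       codes = c(at0101 = "Suspicion",
                                                 at0102 = "Certainty"))),
                      c(sk$p_diag, sk$p_onset, sk$p_confidence))),
    archetype_schema(sk$contra, "EVALUATION", contra_elements),
    archetype_schema(sk$alert, "EVALUATION",
      stats::setNames(list(element_def("boolean"), element_def("boolean"),
                           element_def("boolean"), element_def("boolean")),
                      sprintf("/data[at0001]/items[at%04d]", 10:13))),
    archetype_schema(sk$imaging, "INSTRUCTION",
      stats::setNames(list(cel(), cel()), c(sk$p_img_findings, sk$p_img_site))),
    archetype_schema(sk$medication, "INSTRUCTION",
      stats::setNames(list(cel(), element_def("date_time")),
                      c(sk$p_med, sk$p_med_start))),
    archetype_schema(sk$procedure, "ACTION",
      stats::setNames(list(cel(), element_def("date_time")),
                      c(sk$p_proc, sk$p_proc_time))),
    archetype_schema(sk$ivf, "ACTION",
      stats::setNames(list(cel(), element_def("date_time")),
                      c(sk$p_fluid, sk$p_fluid_time))),
    archetype_schema(sk$gas, "ACTION",
      stats::setNames(list(cel(),
                           element_def("coded_text",
                                       codes = c(at0006 = "Nasal canula",
                                                 at0007 = "Face mask")),
                           element_def("date_time")),
                      c(sk$p_gas, sk$p_gas_means, sk$p_gas_time))),
    # tree archetypes whose elements are flattened into their host entries
    archetype_schema(sk$tree_imaging, "INSTRUCTION"),
    archetype_schema(sk$tree_medication, "INSTRUCTION")
  )
}

#' Registry of the sixteen stroke archetype schemas
#'
#' @return A [schema_registry()] holding all sixteen schemas.
#' @export
stroke_schema_registry <- function() {
  reg <- schema_registry()
  for (s in stroke_schemas()) register_schema(reg, s)
  reg
}

#' Export or load a schema registry as a YAML config file
#'
#' The exported file mirrors the registry one schema per list entry; loading
#' it back reproduces the registry. A copy for the stroke content ships in
#' the package's `extdata` directory.
#'
#' @param registry A [schema_registry()].
#' @param path YAML file path.
#' @return `save_schema_registry()` returns `path` invisibly;
#'   `load_schema_registry()` the registry.
#' @export
save_schema_registry <- function(registry, path) {
  out <- lapply(schema_ids(registry), function(id) {
    s <- get_schema(registry, id)
    list(archetype_id = s$archetype_id, entry_type = s$entry_type,
         elements = lapply(s$elements, function(d) {
           e <- list(kind = d$kind)
           if (!is.null(d$unit)) e$unit <- d$unit
           if (!is.null(d$codes)) e$codes <- as.list(d$codes)
           e
         }))
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname save_schema_registry
#' @export
load_schema_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  reg <- schema_registry()
  for (x in raw) {
    elements <- lapply(x$elements, function(d) {
      element_def(d$kind, unit = d$unit,
                  codes = if (!is.null(d$codes)) unlist(d$codes))
    })
    register_schema(reg, archetype_schema(x$archetype_id, x$entry_type,
                                          elements %||% list()))
  }
  reg
}

#' Terminology subset shipped with the stroke content
#'
#' Loads the packaged SNOMED CT / ICD-10 / ATC / local tables. Only a
#' handful of the codes are fixed by the source material; the remainder is a
#' curated, non-normative reconstruction sufficient to express the shipped
#' criteria (see the README in the terminology data directory).
#'
#' @return A [terminology_store()].
#' @export
stroke_terminology <- function() {
  load_terminology(system.file("extdata", "terminology", package = "strokecds"))
}

#' Catalogue of the nineteen thrombolysis contraindications
#'
#' One row per criterion in source order, with the shipped representation
#' status: fourteen are expressed as rules, five are catalogued but not
#' representable without further clinical consensus (vague wording or
#' missing temporal anchors) and are never evaluated.
#'
#' @return Tibble with columns `criterion_id`, `title`, `represented`,
#'   `flag_gt` (output code in the thrombolysis guideline, `NA` when not
#'   represented), `flag_path` (element in the contraindications evaluation).
#' @export
criterion_specs <- function() {
  spec <- tibble::tribble(
    ~criterion_id, ~represented, ~title,
    "onset_over_4_5h", TRUE, "Stroke onset more than 4.5 hours ago",
    "other_aetiology_or_recovery", FALSE,
      "Symptom presentation suggesting another aetiology than that of stroke and/or the patient recovered within 30 minutes",
    "unclear_symptoms", FALSE, "Unclear stroke symptoms",
    "nihss_over_25", TRUE,
      "National Institutes of Health Stroke Scale (NIHSS) score higher than 25",
    "ct_haemorrhage", TRUE, "CT scan shows haemorrhage",
    "mca_over_30pct", FALSE,
      "CT scan shows major stroke that covers more than 30% of the middle cerebral artery",
    "glucose_out_of_range", TRUE,
      "Blood glucose is lower than 3 mmol/litre or higher than 22 mmol/litre",
    "bp_over_185_110", FALSE,
      "Blood pressure is higher than 185/110 mmHg despite two attempts of intravenous beta-blocking bolus treatment",
    "history_intracranial_haemorrhage", TRUE,
      "History of cerebral haemorrhage or intracranial bleeding",
    "explosive_headache", TRUE,
      "Patient describes an explosive headache (that resembles a subarachnoid haemorrhage)",
    "recent_severe_haemorrhage", FALSE,
      "Ongoing or recent severe haemorrhage (extracranial or intracranial)",
    "postictal_paresis", TRUE, "Likely postictal paresis",
    "septic_shock", TRUE, "Suspected septic shock",
    "bleeding_disorder_or_anticoagulation", TRUE,
      "Bleeding disorder or anticoagulation treatment",
    "serious_comorbidity", TRUE,
      "One of the following: infectious endocarditis, pericarditis, ventricular thrombosis, atrial septal aneurysm, severe heart failure, pancreatitis, severe liver damage",
    "lastweek_lp_cvc", TRUE,
      "One of the following in the last week: lumbar puncture, central venous catheter",
    "lastmonth_organ_or_bleeding", TRUE,
      "One of the following in the last month: operation/biopsy from parenchymatous organs, trauma with internal injuries, duodenal ulcer, bleeding from the urinary tract",
    "last3months_stroke_trauma_op_gi", TRUE,
      "One of the following in the last three months: stroke, head trauma, operation in the central nervous system, definite gastrointestinal bleeding",
    "pregnancy_childbirth_breastfeeding", TRUE,
      "Pregnancy, childbirth in the last month, breastfeeding (relative contraindications)"
  )
  rep_idx <- which(spec$represented)
  spec$flag_gt <- NA_character_
  spec$flag_gt[rep_idx] <- sprintf("gt9%03d", seq_along(rep_idx))
  spec$flag_path <- NA_character_
  spec$flag_path[rep_idx] <- sprintf("/data[at0001]/items[at%04d]",
                                     seq_along(rep_idx) + 1L)
  spec
}

#' Catalogue of the European-guideline compliance criteria
#'
#' @return Tibble with `criterion_id`, `title`, `flag_gt` (`NA` for the
#'   oxygen recommendation, which is reported through the gas-administration
#'   outputs rather than a boolean flag).
#' @export
euro_criterion_specs <- function() {
  tibble::tribble(
    ~criterion_id, ~flag_gt, ~title,
    "euro_mri_justified", "gt9101",
      "An MRI of the brain is justified (posterior circulation varieties or uncommon aetiologies on examination, or a suspected but not excluded stroke mimic on CT)",
    "euro_thrombolysis_indicated", "gt9102",
      "Thrombolysis needs to be performed if examination reveals a deficit related to acute cerebral ischaemia within 4.5 hours as of stroke onset",
    "euro_temp_monitoring", "gt9103",
      "Body temperature should be monitored within the first 72 hours after stroke onset",
    "euro_pyrexia_alert", "gt9104",
      "Body temperature within the monitoring window exceeds 37.5 degrees Celsius",
    "euro_oxygen_recommendation", NA_character_,
      "If oxygen saturation is below 95% then oxygen should be administered"
  )
}

# --- guideline builders ----------------------------------------------------

#' Build the thrombolysis-contraindications guideline
#'
#' Fourteen boolean contraindication flags, each governed by one or more
#' set-true rules (any qualifying entry combination raises the flag) and one
#' guarded set-false rule (fires only when the flag is still unset and the
#' case holds enough data to exclude the criterion). Diagnosis-history
#' look-backs exclude events within 24 hours of the evaluation instant so
#' that the index stroke itself does not count as "stroke in the last three
#' months"; procedure look-backs use the full window.
#'
#' @return A validated guideline; validation failure is a build error.
#' @export
build_thrombolysis_guideline <- function() {
  b <- list(
    gdl_binding("gt0003", sk$diagnosis, sk$p_diag, "input"),
    gdl_binding("gt0004", sk$diagnosis, sk$p_onset, "input"),
    gdl_binding("gt0008", sk$nihss, sk$p_nihss_total, "input"),
    gdl_binding("gt0010", sk$glucose, sk$p_glucose, "input"),
    gdl_binding("gt0011", sk$imaging, sk$p_img_findings, "input"),
    gdl_binding("gt0012", sk$imaging, sk$p_img_site, "input"),
    gdl_binding("gt0013", sk$procedure, sk$p_proc, "input"),
    gdl_binding("gt0014", sk$procedure, sk$p_proc_time, "input"),
    gdl_binding("gt0015", sk$medication, sk$p_med, "input")
  )
  cs <- criterion_specs()
  rep <- cs[cs$represented, ]
  for (i in seq_len(nrow(rep))) {
    b[[length(b) + 1L]] <- gdl_binding(rep$flag_gt[i], sk$contra,
                                       rep$flag_path[i], "output")
  }
  tg <- list(
    term_group("gt0102", "stroke",
               list("ICD10" = "I64", "SNOMED-CT" = "230690007")),
    term_group("gt0103", "cerebral haemorrhage or intracranial bleeding",
               list("ICD10" = c("I61", "I62"),
                    "SNOMED-CT" = c("274100004", "1386000"))),
    term_group("gt0104", "explosive headache",
               list("SNOMED-CT" = "21794005")),
    term_group("gt0105", "postictal paresis",
               list("SNOMED-CT" = "66264000", "ICD10" = "G83.8")),
    term_group("gt0106", "septic shock",
               list("SNOMED-CT" = "76571007", "ICD10" = "R57.2")),
    term_group("gt0107", "bleeding disorder",
               list("SNOMED-CT" = "64779008", "ICD10" = "D68")),
    term_group("gt0108", "anticoagulant treatment",
               list("ATC" = c("B01AA", "B01AB", "B01AF"))),
    term_group("gt0109", "serious cardiac, hepatic or pancreatic condition",
               list("SNOMED-CT" = c("61420007", "3238004", "111293003",
                                    "253416000", "84114007", "75694006",
                                    "235856003"),
                    "ICD10" = c("I33", "I30", "I51.3", "I50", "K85", "K72"))),
    term_group("gt0110", "lumbar puncture or central venous catheter",
               list("SNOMED-CT" = c("45036003", "392247006"))),
    term_group("gt0111", "last-month risk diagnosis",
               list("SNOMED-CT" = c("283545005", "51868009", "34436003"),
                    "ICD10" = c("S36", "K26", "R31"))),
    term_group("gt0112", "operation or biopsy of parenchymatous organ",
               list("SNOMED-CT" = c("86273004", "112746006"))),
    term_group("gt0113", "head trauma or gastrointestinal bleeding",
               list("SNOMED-CT" = c("82271004", "74474003"),
                    "ICD10" = c("S09", "K92.2"))),
    term_group("gt0114", "operation in the central nervous system",
               list("SNOMED-CT" = "25353009")),
    term_group("gt0115", "pregnancy or breastfeeding",
               list("SNOMED-CT" = c("77386006", "169750002"),
                    "ICD10" = c("Z33", "Z39.1"))),
    term_group("gt0116", "childbirth",
               list("SNOMED-CT" = "386216000", "ICD10" = "O80")),
    term_group("gt0117", "haemorrhage (imaging finding)",
               list("SNOMED-CT" = "50960005")),
    term_group("gt0118", "brain (anatomical site)",
               list("SNOMED-CT" = "12738006"))
  )
  tt <- function(id, when, then) gdl_rule(id, when, then, priority = 10L)
  ff <- function(id, when, then) gdl_rule(id, when, then, priority = 1L)
  rules <- list(
    tt("onset_window_true",
       c("$gt0003 is_a local::gt0102|stroke|",
         "$gt0004+PT4H30M<currentDateTime"),
       "$gt9001=true"),
    ff("onset_window_false",
       c("$gt0003 is_a local::gt0102|stroke|",
         "$gt0004+PT4H30M>=currentDateTime", "!exists($gt9001)"),
       "$gt9001=false"),
    tt("nihss_high_true", "$gt0008>25", "$gt9002=true"),
    ff("nihss_high_false", c("$gt0008<=25", "!exists($gt9002)"),
       "$gt9002=false"),
    tt("ct_haemorrhage_true",
       c("$gt0011 is_a local::gt0117|haemorrhage|",
         "$gt0012 is_a local::gt0118|brain|"),
       "$gt9003=true"),
    ff("ct_haemorrhage_false",
       c("!($gt0011 is_a local::gt0117|haemorrhage| && $gt0012 is_a local::gt0118|brain|)",
         "!exists($gt9003)"),
       "$gt9003=false"),
    tt("glucose_range_true", "$gt0010<3 || $gt0010>22", "$gt9004=true"),
    ff("glucose_range_false",
       c("$gt0010>=3", "$gt0010<=22", "!exists($gt9004)"), "$gt9004=false"),
    tt("ich_history_true",
       "$gt0003 is_a local::gt0103|cerebral haemorrhage or intracranial bleeding|",
       "$gt9005=true"),
    ff("ich_history_false",
       c("!($gt0003 is_a local::gt0103|cerebral haemorrhage or intracranial bleeding|)",
         "!exists($gt9005)"),
       "$gt9005=false"),
    tt("explosive_headache_true",
       "$gt0003 is_a local::gt0104|explosive headache|", "$gt9006=true"),
    ff("explosive_headache_false",
       c("!($gt0003 is_a local::gt0104|explosive headache|)", "!exists($gt9006)"),
       "$gt9006=false"),
    tt("postictal_paresis_true",
       "$gt0003 is_a local::gt0105|postictal paresis|", "$gt9007=true"),
    ff("postictal_paresis_false",
       c("!($gt0003 is_a local::gt0105|postictal paresis|)", "!exists($gt9007)"),
       "$gt9007=false"),
    tt("septic_shock_true",
       "$gt0003 is_a local::gt0106|septic shock|", "$gt9008=true"),
    ff("septic_shock_false",
       c("!($gt0003 is_a local::gt0106|septic shock|)", "!exists($gt9008)"),
       "$gt9008=false"),
    tt("bleeding_dx_true",
       "$gt0003 is_a local::gt0107|bleeding disorder|", "$gt9009=true"),
    tt("anticoagulation_true",
       "$gt0015 is_a local::gt0108|anticoagulant treatment|", "$gt9009=true"),
    ff("bleeding_or_anticoag_false",
       c("!($gt0003 is_a local::gt0107|bleeding disorder|)",
         "!($gt0015 is_a local::gt0108|anticoagulant treatment|)",
         "!exists($gt9009)"),
       "$gt9009=false"),
    tt("comorbidity_true",
       "$gt0003 is_a local::gt0109|serious cardiac, hepatic or pancreatic condition|",
       "$gt9010=true"),
    ff("comorbidity_false",
       c("!($gt0003 is_a local::gt0109|serious cardiac, hepatic or pancreatic condition|)",
         "!exists($gt9010)"),
       "$gt9010=false"),
    tt("lastweek_proc_true",
       c("$gt0013 is_a local::gt0110|lumbar puncture or central venous catheter|",
         "$gt0014+PT168H>currentDateTime"),
       "$gt9011=true"),
    ff("lastweek_proc_false",
       c("!($gt0013 is_a local::gt0110|lumbar puncture or central venous catheter| && $gt0014+PT168H>currentDateTime)",
         "!exists($gt9011)"),
       "$gt9011=false"),
    tt("lastmonth_dx_true",
       c("$gt0003 is_a local::gt0111|last-month risk diagnosis|",
         "$gt0004+PT720H>currentDateTime"),
       "$gt9012=true"),
    tt("lastmonth_proc_true",
       c("$gt0013 is_a local::gt0112|operation or biopsy of parenchymatous organ|",
         "$gt0014+PT720H>currentDateTime"),
       "$gt9012=true"),
    ff("lastmonth_false",
       c("!($gt0003 is_a local::gt0111|last-month risk diagnosis| && $gt0004+PT720H>currentDateTime)",
         "!($gt0013 is_a local::gt0112|operation or biopsy of parenchymatous organ| && $gt0014+PT720H>currentDateTime)",
         "!exists($gt9012)"),
       "$gt9012=false"),
    tt("last3months_prior_stroke_true",
       c("$gt0003 is_a local::gt0102|stroke|",
         "$gt0004+PT2160H>currentDateTime",
         "$gt0004+PT24H<currentDateTime"),
       "$gt9013=true"),
    tt("last3months_dx_true",
       c("$gt0003 is_a local::gt0113|head trauma or gastrointestinal bleeding|",
         "$gt0004+PT2160H>currentDateTime"),
       "$gt9013=true"),
    tt("last3months_proc_true",
       c("$gt0013 is_a local::gt0114|operation in the central nervous system|",
         "$gt0014+PT2160H>currentDateTime"),
       "$gt9013=true"),
    ff("last3months_false",
       c("!($gt0003 is_a local::gt0102|stroke| && $gt0004+PT2160H>currentDateTime && $gt0004+PT24H<currentDateTime)",
         "!($gt0003 is_a local::gt0113|head trauma or gastrointestinal bleeding| && $gt0004+PT2160H>currentDateTime)",
         "!($gt0013 is_a local::gt0114|operation in the central nervous system| && $gt0014+PT2160H>currentDateTime)",
         "!exists($gt9013)"),
       "$gt9013=false"),
    tt("pregnancy_true",
       "$gt0003 is_a local::gt0115|pregnancy or breastfeeding|", "$gt9014=true"),
    tt("childbirth_true",
       c("$gt0003 is_a local::gt0116|childbirth|",
         "$gt0004+PT720H>currentDateTime"),
       "$gt9014=true"),
    ff("pregnancy_related_false",
       c("!($gt0003 is_a local::gt0115|pregnancy or breastfeeding|)",
         "!($gt0003 is_a local::gt0116|childbirth| && $gt0004+PT720H>currentDateTime)",
         "!exists($gt9014)"),
       "$gt9014=false")
  )
  g <- new_guideline(
    "stroke.thrombolysis_contraindications",
    description = paste(
      "Retrospective screen for fourteen contraindications to thrombolytic",
      "treatment of acute ischaemic stroke, anchored to the thrombolysis",
      "decision time."),
    bindings = b, term_groups = tg, rules = rules)
  assert_valid_guideline(g)
}

#' Build the NIHSS score-derivation guideline
#'
#' One rule per answer level of each of the fifteen items maps the coded
#' answer to its integer contribution (57 rules), and a final summation rule
#' derives the total score (0-42) once every contribution is known: 58 rules
#' in all.
#'
#' @return A validated guideline.
#' @export
build_nihss_guideline <- function() {
  items <- nihss_items()
  b <- list()
  rules <- list()
  for (k in items$item) {
    in_code <- sprintf("gt1%03d", k)
    out_code <- sprintf("gt2%03d", k)
    b[[length(b) + 1L]] <- gdl_binding(in_code, sk$nihss, items$path[k], "input")
    b[[length(b) + 1L]] <- gdl_binding(out_code, sk$nihss,
                                       nihss_contrib_path(k), "output")
    for (l in 0:(items$n_levels[k] - 1L)) {
      rules[[length(rules) + 1L]] <- gdl_rule(
        sprintf("nihss_item%02d_level%d", k, l),
        when = sprintf("$%s==local::%s|%s, score %d|", in_code,
                       nihss_level_code(k, l), items$name[k], l),
        then = sprintf("$%s=%d", out_code, l),
        priority = 10L)
    }
  }
  b[[length(b) + 1L]] <- gdl_binding("gt2100", sk$nihss, sk$p_nihss_total,
                                     "output")
  rules[[length(rules) + 1L]] <- gdl_rule(
    "nihss_total_sum",
    then = paste0("$gt2100=", paste(sprintf("$gt2%03d", items$item),
                                    collapse = "+")),
    priority = 1L)
  g <- new_guideline(
    "stroke.nihss_score",
    description = paste(
      "Derives each NIHSS item's integer contribution from its coded answer",
      "and sums the contributions into the total score."),
    bindings = b, rules = rules)
  assert_valid_guideline(g)
}

#' Build the European-guideline compliance criteria guideline
#'
#' Six rules sampled from European acute-stroke management recommendations:
#' two disjunct MRI-justification rules, a thrombolysis-indication rule
#' (ischaemic deficit within 4.5 h of onset), temperature-monitoring and
#' pyrexia rules over the first 72 h after onset, and an oxygen rule that
#' recommends administration (nasal cannula) when SpO2 is below 95%.
#'
#' @return A validated guideline.
#' @export
build_euro_criteria_guideline <- function() {
  b <- list(
    gdl_binding("gt0003", sk$diagnosis, sk$p_diag, "input"),
    gdl_binding("gt0004", sk$diagnosis, sk$p_onset, "input"),
    gdl_binding("gt0020", sk$exam, sk$p_exam, "input"),
    gdl_binding("gt0021", sk$imaging, sk$p_img_findings, "input"),
    gdl_binding("gt0022", sk$temp, sk$p_temp, "input"),
    gdl_binding("gt0023", sk$temp, sk$p_temp_time, "input"),
    gdl_binding("gt0024", sk$oximetry, sk$p_spo2, "input"),
    gdl_binding("gt9101", sk$alert, "/data[at0001]/items[at0010]", "output"),
    gdl_binding("gt9102", sk$alert, "/data[at0001]/items[at0011]", "output"),
    gdl_binding("gt9103", sk$alert, "/data[at0001]/items[at0012]", "output"),
    gdl_binding("gt9104", sk$alert, "/data[at0001]/items[at0013]", "output"),
    gdl_binding("gt9105", sk$gas, sk$p_gas, "output"),
    gdl_binding("gt9106", sk$gas, sk$p_gas_means, "output")
  )
  tg <- list(
    term_group("gt0102", "stroke",
               list("ICD10" = "I64", "SNOMED-CT" = "230690007")),
    term_group("gt0201", "posterior circulation variety or uncommon aetiology",
               list("SNOMED-CT" = c("95460007", "472916000"))),
    term_group("gt0202", "suspected stroke mimic",
               list("SNOMED-CT" = "709491003")),
    term_group("gt0203", "deficit related to acute cerebral ischaemia",
               list("SNOMED-CT" = "432504007"))
  )
  rules <- list(
    gdl_rule("mri_exam_justified",
             "$gt0020 is_a local::gt0201|posterior circulation variety or uncommon aetiology|",
             "$gt9101=true", priority = 10L),
    gdl_rule("mri_imaging_justified",
             "$gt0021 is_a local::gt0202|suspected stroke mimic|",
             "$gt9101=true", priority = 10L),
    gdl_rule("thrombolysis_indicated",
             c("$gt0020 is_a local::gt0203|deficit related to acute cerebral ischaemia|",
               "$gt0003 is_a local::gt0102|stroke|",
               "$gt0004+PT4H30M>currentDateTime"),
             "$gt9102=true", priority = 10L),
    gdl_rule("temp_monitored",
             c("$gt0003 is_a local::gt0102|stroke|",
               "$gt0023>=$gt0004", "$gt0023<$gt0004+PT72H"),
             "$gt9103=true", priority = 10L),
    gdl_rule("pyrexia_alert",
             c("$gt0003 is_a local::gt0102|stroke|", "$gt0022>37.5",
               "$gt0023>=$gt0004", "$gt0023<$gt0004+PT72H"),
             "$gt9104=true", priority = 10L),
    gdl_rule("oxygen_recommended",
             "$gt0024<95",
             c("$gt9105=SNOMED-CT::24099007|Oxygen|",
               "$gt9106=local::at0006|Nasal canula|"),
             priority = 10L)
  )
  g <- new_guideline(
    "stroke.euro_compliance_criteria",
    description = paste(
      "Sample of compliance criteria from European guidelines for ischaemic",
      "stroke management: MRI justification, thrombolysis indication,",
      "temperature monitoring with a 37.5 degree Celsius pyrexia alert, and oxygen",
      "administration below 95% saturation."),
    bindings = b, term_groups = tg, rules = rules)
  assert_valid_guideline(g)
}

assert_valid_guideline <- function(g) {
  v <- validate_guideline(g, stroke_schema_registry(), stroke_terminology())
  if (nrow(v)) {
    stop("guideline ", g$guideline_id, " failed validation:\n",
         paste(utils::capture.output(print(as.data.frame(v))), collapse = "\n"),
         call. = FALSE)
  }
  g
}

#' The three shipped stroke guidelines
#'
#' Convenience accessor returning the validated guideline objects; the
#' corresponding `.gdl` files in the package's `extdata/guidelines`
#' directory are their serializations.
#'
#' @param which One of `"thrombolysis"`, `"nihss"`, `"euro"`; or omit for
#'   all three as a named list.
#' @return A guideline or a named list of the three.
#' @export
stroke_guidelines <- function(which = NULL) {
  all <- list(thrombolysis = build_thrombolysis_guideline,
              nihss = build_nihss_guideline,
              euro = build_euro_criteria_guideline)
  if (is.null(which)) return(lapply(all, function(f) f()))
  which <- match.arg(which, names(all))
  all[[which]]()
}
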