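# Minimal content for focused engine tests: one diagnosis + one procedure
# input archetype and one boolean output flag.
toy_guideline <- function(rules) {
  new_guideline("toy", bindings = list(
    gdl_binding("gt0003", "openEHR-EHR-EVALUATION.problem_diagnosis",
                "/data[at0001]/items[at0002.1]", "input"),
    gdl_binding("gt0004", "openEHR-EHR-EVALUATION.problem_diagnosis",
                "/data[at0001]/items[at0003]", "input"),
    gdl_binding("gt0013", "openEHR-EHR-ACTION.procedure",
                "/description[at0001]/items[at0002]", "input"),
    gdl_binding("gt9001", "openEHR-EHR-EVALUATION.alert",
                "/data[at0001]/items[at0010]", "output"),
    gdl_binding("gt9002", "openEHR-EHR-EVALUATION.alert",
                "/data[at0001]/items[at0011]", "output")),
    term_groups = list(term_group("gt0102", "stroke",
                                  list("ICD10" = "I64",
                                       "SNOMED-CT" = "230690007"))),
    rules = rules)
}

dx_entry <- function(code_sys, code, when = "2014-01-01T08:00:00Z",
                     onset = NULL) {
  els <- setNames(list(dv_coded(code_sys, code, "")),
                  "/data[at0001]/items[at0002.1]")
  if (!is.null(onset)) els[["/data[at0001]/items[at0003]"]] <- dv_datetime(onset)
  new_entry("openEHR-EHR-EVALUATION.problem_diagnosis", when, els)
}

proc_entry2 <- function(code, when = "2014-01-01T08:00:00Z") {
  new_entry("openEHR-EHR-ACTION.procedure", when,
            setNames(list(dv_coded("SNOMED-CT", code, "")),
                     "/description[at0001]/items[at0002]"))
}

test_that("bind_inputs enumerates one entry per input archetype", {
  g <- toy_guideline(list(
    gdl_rule("dx_only", "$gt0003 is_a local::gt0102|stroke|", "$gt9001=true"),
    gdl_rule("join", c("$gt0003 is_a local::gt0102|stroke|",
                       "$gt0013==SNOMED-CT::45036003"), "$gt9002=true")))
  case2 <- patient_case("c", "2014-01-02T00:00:00Z",
                        list(dx_entry("ICD10", "I64"),
                             dx_entry("SNOMED-CT", "38341003")))
  expect_length(bind_inputs(g, case2, "dx_only"), 2L)
  expect_length(bind_inputs(g, case2, "join"), 0L)  # no procedure entries
  case6 <- patient_case("c6", "2014-01-02T00:00:00Z", c(
    case2$entries,
    list(proc_entry2("45036003"), proc_entry2("29303009"),
         proc_entry2("86273004"))))
  expect_length(bind_inputs(g, case6, "join"), 6L)  # 2 diagnoses x 3 procedures
})

test_that("condition evaluation is three-valued with strict comparisons", {
  g <- GUIDELINES$thrombolysis
  mk <- function(total) {
    entries <- if (is.null(total)) list() else list(
      new_entry("openEHR-EHR-OBSERVATION.nihss", "2014-01-01T08:00:00Z",
                setNames(list(dv_count(total)),
                         "/data[at0001]/items[at0090]")))
    patient_case("c", "2014-01-01T12:00:00Z", entries)
  }
  cond <- parse_expression("$gt0008>25")
  ctx_for <- function(case) {
    e <- new.env()
    e$guideline <- g; e$case <- case; e$now <- case$reference_time
    e$wm <- list(); e$store <- STORE
    e
  }
  tup <- function(case) bind_inputs(g, case, "nihss_high_true")[[1]]
  expect_true(eval_condition(cond, ctx_for(mk(26)), tup(mk(26))))
  expect_false(eval_condition(cond, ctx_for(mk(25)), tup(mk(25))))
  # value absent within the entry -> unknown
  empty_entry_case <- patient_case("c", "2014-01-01T12:00:00Z", list(
    new_entry("openEHR-EHR-OBSERVATION.nihss", "2014-01-01T08:00:00Z")))
  expect_true(is.na(eval_condition(cond, ctx_for(empty_entry_case),
                                   bind_inputs(g, empty_entry_case,
                                               "nihss_high_true")[[1]])))
  # quantity thresholds are strict exactly as phrased
  glu_cond <- parse_expression("$gt0010<3")
  glu_case <- function(v) patient_case("c", "2014-01-01T12:00:00Z", list(
    new_entry("openEHR-EHR-OBSERVATION.lab_test-blood_glucose",
              "2014-01-01T08:00:00Z",
              setNames(list(dv_quantity(v, "mmol/l")),
                       "/data[at0001]/items[at0078.1]"))))
  expect_true(eval_condition(glu_cond, ctx_for(glu_case(2.9)),
                             bind_inputs(g, glu_case(2.9),
                                         "glucose_range_true")[[1]]))
  expect_false(eval_condition(glu_cond, ctx_for(glu_case(3)),
                              bind_inputs(g, glu_case(3),
                                          "glucose_range_true")[[1]]))
})

test_that("forward chaining reaches the NIHSS total through item rules", {
  zeros <- rep(0L, 15)
  expect_equal(engine_nihss_total(zeros), 0L)
  maxima <- nihss_items()$max_score
  expect_equal(engine_nihss_total(maxima), 42L)
  one_item <- zeros; one_item[4] <- 2L
  expect_equal(engine_nihss_total(one_item), 2L)
})

test_that("the onset window and oxygen recommendation fire as published", {
  expect_true(probe_flag("onset_hours", 5, PROBE_CONTENT))
  expect_false(probe_flag("onset_hours", 3, PROBE_CONTENT))
  case94 <- probe_case("spo2", 94)
  res <- run_guideline(GUIDELINES$euro, case94, REG, STORE)
  expect_equal(res$outputs[["gt9105"]]$code, "24099007")
  expect_equal(res$outputs[["gt9106"]]$code, "at0006")
  expect_equal(res$outputs[["gt9106"]]$system, "local")
  res96 <- run_guideline(GUIDELINES$euro, probe_case("spo2", 96), REG, STORE)
  expect_null(res96$outputs[["gt9105"]])
})

test_that("fixpoint evaluation is invariant under rule-order permutation", {
  set.seed(777)
  cases <- lapply(c(1, 4, 11, 18, 25), random_generated_case)
  for (g in GUIDELINES[c("thrombolysis", "euro", "nihss")]) {
    for (case in cases[1:3]) {
      ref <- run_guideline(g, case, REG, STORE)
      perm <- g
      perm$rules <- perm$rules[sample(seq_along(perm$rules))]
      alt <- run_guideline(perm, case, REG, STORE)
      expect_equal(lapply(ref$outputs, unclass)[sort(names(ref$outputs))],
                   lapply(alt$outputs, unclass)[sort(names(alt$outputs))],
                   info = g$guideline_id)
      expect_setequal(alt$indeterminate, ref$indeterminate)
    }
  }
})

test_that("missing inputs yield indeterminate flags, never a silent false", {
  base <- random_generated_case(1)  # clean profile
  res <- run_guideline(GUIDELINES$thrombolysis, base, REG, STORE)
  expect_false(flag_value(res, "gt9002"))
  # drop the NIHSS observation: the flag must become indeterminate
  no_nihss <- patient_case(base$case_id, base$reference_time,
                           Filter(function(e) {
                             e$archetype_id != "openEHR-EHR-OBSERVATION.nihss"
                           }, base$entries))
  res2 <- run_guideline(GUIDELINES$thrombolysis, no_nihss, REG, STORE)
  expect_true(is.na(flag_value(res2, "gt9002")))
  expect_true("gt9002" %in% res2$indeterminate)
})

test_that("adding a qualifying diagnosis never clears a raised flag", {
  case <- random_generated_case(7)  # prior intracranial haemorrhage
  res <- run_guideline(GUIDELINES$thrombolysis, case, REG, STORE)
  expect_true(flag_value(res, "gt9005"))
  more <- patient_case(case$case_id, case$reference_time, c(
    case$entries, list(dx_entry("ICD10", "I61", onset = "2013-01-01T00:00:00Z"))))
  res2 <- run_guideline(GUIDELINES$thrombolysis, more, REG, STORE)
  expect_true(flag_value(res2, "gt9005"))
})

test_that("assignment cycles hit the iteration guard", {
  g <- new_guideline("cyclic", bindings = list(
    gdl_binding("gt9001", "openEHR-EHR-EVALUATION.alert",
                "/data[at0001]/items[at0010]", "output")),
    rules = list(
      gdl_rule("set_true", then = "$gt9001=true", priority = 2L),
      gdl_rule("flip", "$gt9001==true", "$gt9001=false", priority = 1L)))
  case <- patient_case("c", "2014-01-01T00:00:00Z")
  expect_error(run_guideline(g, case, REG, STORE), "fixpoint")
})
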