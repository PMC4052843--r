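test_that("the contraindication catalogue matches the published yes/no split", {
  cs <- criterion_specs()
  expect_equal(nrow(cs), 19L)
  expect_equal(sum(cs$represented), 14L)
  expect_equal(sum(!cs$represented), 5L)
  expect_equal(cs$criterion_id[!cs$represented],
               c("other_aetiology_or_recovery", "unclear_symptoms",
                 "mca_over_30pct", "bp_over_185_110",
                 "recent_severe_haemorrhage"))
  # unrepresented criteria have no output binding and are never evaluated
  expect_true(all(is.na(cs$flag_gt[!cs$represented])))
  bound <- vapply(build_thrombolysis_guideline()$bindings, `[[`, character(1),
                  "direction")
  expect_equal(sum(bound == "output"), 14L)
})

test_that("all three shipped guidelines validate with zero violations", {
  for (g in GUIDELINES) {
    expect_equal(nrow(validate_guideline(g, REG, STORE)), 0L,
                 info = g$guideline_id)
  }
  expect_equal(length(GUIDELINES$nihss$rules), 58L)
  expect_equal(length(GUIDELINES$euro$rules), 6L)
})

test_that("look-back windows include and exclude history as specified", {
  t0 <- parse_iso_datetime("2014-06-01T12:00:00Z")
  ecg <- new_entry("openEHR-EHR-ACTION.procedure", t0 - 3600,
                   setNames(list(dv_coded("SNOMED-CT", "29303009", "ECG"),
                                 dv_datetime(t0 - 3600)),
                            c("/description[at0001]/items[at0002]",
                              "/description[at0001]/items[at0049]")))
  mk_hist <- function(extra_entries) {
    base <- probe_case("glucose", 5)  # stroke dx 2 h back + normal glucose
    patient_case("hist", base$reference_time,
                 c(base$entries, list(ecg), extra_entries))
  }
  lp <- function(days_back) {
    new_entry("openEHR-EHR-ACTION.procedure", t0 - days_back * 86400,
              setNames(list(dv_coded("SNOMED-CT", "45036003", "Lumbar puncture"),
                            dv_datetime(t0 - days_back * 86400)),
                       c("/description[at0001]/items[at0002]",
                         "/description[at0001]/items[at0049]")))
  }
  run <- function(case) run_guideline(GUIDELINES$thrombolysis, case, REG, STORE)
  # lumbar puncture five days back: within the 168 h window
  expect_true(flag_value(run(mk_hist(list(lp(5)))), "gt9011"))
  # eight days back: outside the window, flag explicitly false
  expect_false(flag_value(run(mk_hist(list(lp(8)))), "gt9011"))

  prior_stroke <- function(days_back) {
    new_entry("openEHR-EHR-EVALUATION.problem_diagnosis",
              t0 - (days_back - 1) * 86400,
              setNames(list(dv_coded("SNOMED-CT", "230690007", "CVA"),
                            dv_datetime(t0 - days_back * 86400)),
                       c("/data[at0001]/items[at0002.1]",
                         "/data[at0001]/items[at0003]")))
  }
  # stroke 80 days before the decision: inside the three-month window
  expect_true(flag_value(run(mk_hist(list(prior_stroke(80)))), "gt9013"))
  # stroke 100 days before: outside
  expect_false(flag_value(run(mk_hist(list(prior_stroke(100)))), "gt9013"))
  # the index stroke itself (2 h old) does not count as history
  expect_false(flag_value(run(mk_hist(list())), "gt9013"))
})

test_that("glucose, NIHSS and pyrexia boundaries are strict as phrased", {
  expect_true(probe_flag("glucose", 2.999, PROBE_CONTENT))
  expect_false(probe_flag("glucose", 3, PROBE_CONTENT))
  expect_false(probe_flag("glucose", 22, PROBE_CONTENT))
  expect_true(probe_flag("glucose", 22.001, PROBE_CONTENT))
  expect_false(probe_flag("nihss_total", 25, PROBE_CONTENT))
  expect_true(probe_flag("nihss_total", 26, PROBE_CONTENT))
  expect_false(probe_flag("temperature", 37.5, PROBE_CONTENT))
  expect_true(probe_flag("temperature", 37.6, PROBE_CONTENT))
  expect_true(probe_flag("temp_offset_hours", 71.9, PROBE_CONTENT))
  expect_false(probe_flag("temp_offset_hours", 72, PROBE_CONTENT))
})

test_that("imaging haemorrhage needs both the finding and the brain site", {
  t0 <- "2014-06-01T12:00:00Z"
  img <- function(findings, site) {
    els <- list()
    if (!is.null(findings)) {
      els[["/activities[at0001]/description[at0002]/items[at0003]"]] <-
        dv_coded("SNOMED-CT", findings, "")
    }
    if (!is.null(site)) {
      els[["/activities[at0001]/description[at0002]/items[at0007]"]] <-
        dv_coded("SNOMED-CT", site, "")
    }
    patient_case("img", t0, list(
      new_entry("openEHR-EHR-INSTRUCTION.imaging", "2014-06-01T10:00:00Z", els)))
  }
  run <- function(case) run_guideline(GUIDELINES$thrombolysis, case, REG, STORE)
  expect_true(flag_value(run(img("50960005", "12738006")), "gt9003"))
  expect_false(flag_value(run(img("281900007", "12738006")), "gt9003"))
  # haemorrhage finding with the site element missing: cannot be decided
  expect_true(is.na(flag_value(run(img("50960005", NULL)), "gt9003")))
})
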