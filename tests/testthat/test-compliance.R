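test_that("the oracle applies the published glucose bounds strictly", {
  glu_case <- function(v) {
    base <- probe_case("glucose", v)
    patient_case("g", base$reference_time, base$entries)
  }
  st <- function(v) {
    o <- oracle_check(glu_case(v), STORE)
    o$status[o$criterion_id == "glucose_out_of_range"]
  }
  expect_equal(st(2.9), "triggered")
  expect_equal(st(3.0), "not_triggered")
  expect_equal(st(22.0), "not_triggered")
  expect_equal(st(22.1), "triggered")
})

test_that("comparison is reflexive and sensitive to single-cell mutations", {
  cases <- lapply(1:4, random_generated_case)
  verdicts <- dplyr::bind_rows(lapply(cases, function(case) {
    dplyr::mutate(oracle_check(case, STORE), case_id = case$case_id,
                  .before = 1)
  }))
  self <- compare_verdicts(verdicts, verdicts)
  expect_equal(self$n_match, 4L)
  expect_equal(self$prop_match, 1)
  mutated <- verdicts
  mutated$status[7] <- setdiff(c("triggered", "not_triggered"),
                               mutated$status[7])[1]
  diff <- compare_verdicts(verdicts, mutated)
  expect_equal(diff$n_match, 3L)
  expect_equal(nrow(diff$discrepancies), 1L)
  expect_error(compare_verdicts(verdicts,
                                dplyr::filter(verdicts, case_id != "fuzz_1")),
               "different case ids")
})

test_that("audit aggregates verdicts with conserved counts", {
  cases <- generate_cohort(10)
  report <- audit(cases, GUIDELINES, REG, STORE)
  expect_s3_class(report, "strokecds_report")
  counts <- report$criterion_counts
  expect_equal(nrow(counts), 19L)
  expect_true(all(counts$triggered + counts$not_triggered +
                    counts$indeterminate == 10L))
  expect_lte(report$non_compliance_count, report$n_cases)
  expect_equal(nrow(report$case_summary), 10L)
  # broom-style accessors
  expect_equal(nrow(tidy(report)), 190L)
  expect_equal(glance(report)$n_cases, 10L)
  expect_s3_class(autoplot(report), "ggplot")
})

test_that("an empty cohort yields an all-zero report", {
  report <- audit(list(), GUIDELINES, REG, STORE)
  expect_equal(report$n_cases, 0L)
  expect_equal(report$non_compliance_count, 0L)
  expect_equal(nrow(report$verdicts), 0L)
})

test_that("unreadable case files are recorded and the audit continues", {
  dir <- withr::local_tempdir()
  write_cohort(generate_cohort(3), dir)
  writeLines("case_id = <", file.path(dir, "mangled.case.dadl"))
  report <- audit(dir, GUIDELINES, REG, STORE)
  expect_equal(report$n_cases, 3L)
  expect_equal(nrow(report$case_errors), 1L)
})

test_that("thrombolysis administration is detected through the ATC subtree", {
  given <- generate_case("anticoagulated", 5)
  expect_true(thrombolysis_given(given, STORE))
  not_given <- generate_case("glucose_low", 5)
  expect_false(thrombolysis_given(not_given, STORE))
})

test_that("engine and oracle verdict vectors agree on 1000 fuzzed cases", {
  n <- 1000L
  mismatches <- 0L
  for (i in seq_len(n)) {
    case <- random_generated_case(i)
    ev <- engine_verdicts(case, GUIDELINES, REG, STORE)
    ov <- oracle_check(case, STORE)
    if (!identical(ev$status, ov$status)) {
      mismatches <- mismatches + 1L
      if (mismatches <= 3L) {
        print(case$case_id)
        print(cbind(ev, oracle = ov$status)[ev$status != ov$status, ])
      }
    }
  }
  expect_equal(mismatches, 0L)
})
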