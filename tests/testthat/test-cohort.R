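test_that("case generation is deterministic in (profile, seed)", {
  a <- generate_case("nihss_high", 11)
  b <- generate_case("nihss_high", 11)
  expect_true(case_equal(a, b))
  expect_identical(write_case(a), write_case(b))
  c2 <- generate_case("nihss_high", 12)
  expect_false(identical(write_case(a), write_case(c2)))
})

test_that("the default cohort is reproducible byte for byte", {
  s1 <- vapply(generate_cohort(49), write_case, character(1))
  s2 <- vapply(generate_cohort(49), write_case, character(1))
  expect_identical(s1, s2)
  other <- vapply(generate_cohort(49, master_seed = 999), write_case,
                  character(1))
  expect_false(all(s1 == other))
})

test_that("cohort sizing and argument checks behave", {
  expect_length(generate_cohort(1), 1L)
  expect_error(generate_cohort(0), "positive")
  ids <- vapply(generate_cohort(5), `[[`, character(1), "case_id")
  expect_false(anyDuplicated(ids) > 0)
})

test_that("every generated case is schema-valid", {
  for (case in generate_cohort(30)) {
    expect_equal(nrow(validate_case(case, REG)), 0L, info = case$case_id)
  }
})

test_that("profile intents are realised in the generated data", {
  high <- generate_case("nihss_high", 3)
  total <- get_value(high, "openEHR-EHR-OBSERVATION.nihss",
                     "/data[at0001]/items[at0090]")[[1]]
  expect_gt(total$value, 25)
  low <- generate_case("glucose_low", 3)
  glu <- get_value(low, "openEHR-EHR-OBSERVATION.lab_test-blood_glucose",
                   "/data[at0001]/items[at0078.1]")[[1]]
  expect_lt(glu$magnitude, 3)
  clean <- generate_case("clean", 3)
  v <- oracle_check(clean, STORE)
  contra <- criterion_specs()$criterion_id[criterion_specs()$represented]
  expect_true(all(v$status[v$criterion_id %in% contra] == "not_triggered"))
})

test_that("a cohort directory round-trips through the file formats", {
  dir <- withr::local_tempdir()
  cases <- generate_cohort(6)
  write_cohort(cases, dir, format = "dadl")
  write_cohort(cases[1:2], dir, format = "json")
  loaded <- read_cohort(dir)
  expect_equal(nrow(loaded$errors), 0L)
  expect_length(loaded$cases, 8L)
  writeLines("entries = <", file.path(dir, "broken.case.dadl"))
  loaded2 <- read_cohort(dir)
  expect_equal(nrow(loaded2$errors), 1L)
  expect_length(loaded2$cases, 8L)
})
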