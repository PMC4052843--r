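test_that("data value constructors enforce their invariants", {
  expect_equal(dv_count(26)$value, 26L)
  expect_error(dv_count(2.5), "integer")
  expect_error(dv_quantity(2.9, ""), "unit")
  expect_equal(dv_quantity(2.9, "mmol/l")$magnitude, 2.9)
  expect_error(dv_boolean(NA), "TRUE or FALSE")
  expect_equal(dv_coded("SNOMED-CT", "50960005", "Haemorrhage")$code, "50960005")
  expect_equal(dv_kind(dv_duration("PT4H30M")), "duration")
  expect_equal(dv_duration("PT4H30M")$seconds, 16200)
  expect_equal(dv_duration("-PT30M")$seconds, -1800)
  expect_error(dv_duration("P1M"), "duration")  # calendar months rejected
})

test_that("timestamps normalise to UTC at second resolution", {
  a <- parse_iso_datetime("2014-03-01T10:30:00Z")
  b <- parse_iso_datetime("2014-03-01T12:30:00+02:00")
  expect_equal(as.numeric(a), as.numeric(b))
  expect_equal(format_iso_datetime(a), "2014-03-01T10:30:00Z")
  expect_error(parse_iso_datetime("2014-03-01 10:30:00"), "ISO 8601")
  expect_error(parse_iso_datetime("2014-03-01T10:30:00"), "ISO 8601")
})

test_that("schema registry registers the sixteen stroke schemas once", {
  reg <- stroke_schema_registry()
  expect_length(schema_ids(reg), 16L)
  dup <- archetype_schema("openEHR-EHR-OBSERVATION.exam", "OBSERVATION")
  expect_error(register_schema(reg, dup), "already registered")
  # an element-free schema is accepted and validates entry type only
  reg2 <- schema_registry()
  register_schema(reg2, archetype_schema("openEHR-EHR-OBSERVATION.empty",
                                         "OBSERVATION"))
  e <- new_entry("openEHR-EHR-OBSERVATION.empty", "2014-01-01T00:00:00Z",
                 entry_type = "EVALUATION")
  expect_equal(validate_entry(e, reg2)$problem, "entry_type")
})

test_that("entry validation checks paths, kinds and fixed units", {
  glu <- "openEHR-EHR-OBSERVATION.lab_test-blood_glucose"
  path <- "/data[at0001]/items[at0078.1]"
  good <- new_entry(glu, "2014-01-01T10:00:00Z",
                    setNames(list(dv_quantity(2.9, "mmol/l")), path))
  expect_equal(nrow(validate_entry(good, REG)), 0L)
  wrong_unit <- new_entry(glu, "2014-01-01T10:00:00Z",
                          setNames(list(dv_quantity(52, "mg/dl")), path))
  expect_equal(validate_entry(wrong_unit, REG)$problem, "unit")
  stray <- new_entry(glu, "2014-01-01T10:00:00Z",
                     setNames(list(dv_count(1)), "/data[at0001]/items[at9999]"))
  expect_equal(validate_entry(stray, REG)$problem, "unknown_path")
  unknown <- new_entry("openEHR-EHR-OBSERVATION.nonexistent",
                       "2014-01-01T10:00:00Z")
  expect_error(validate_entry(unknown, REG), "unknown archetype")
})

test_that("get_value returns all values at a path in event-time order", {
  dx <- "openEHR-EHR-EVALUATION.problem_diagnosis"
  p <- "/data[at0001]/items[at0002.1]"
  e1 <- new_entry(dx, "2014-01-02T00:00:00Z",
                  setNames(list(dv_coded("ICD10", "I64", "Stroke")), p))
  e2 <- new_entry(dx, "2014-01-01T00:00:00Z",
                  setNames(list(dv_coded("SNOMED-CT", "38341003",
                                         "Hypertension")), p))
  case <- patient_case("c", "2014-01-03T00:00:00Z", list(e1, e2))
  vals <- get_value(case, dx, p)
  expect_length(vals, 2L)
  expect_equal(vals[[1]]$code, "38341003")  # earlier event first
  expect_length(get_value(case, "openEHR-EHR-INSTRUCTION.imaging",
                          "/activities[at0001]/description[at0002]/items[at0003]"),
                0L)
})

test_that("imaging findings round the trip through the dADL dialect", {
  img <- "openEHR-EHR-INSTRUCTION.imaging"
  case <- patient_case("fig8", "2014-01-01T12:00:00Z", list(
    new_entry(img, "2014-01-01T11:00:00Z", setNames(
      list(dv_coded("SNOMED-CT", "50960005", "Haemorrhage"),
           dv_coded("SNOMED-CT", "12738006", "Brain")),
      c("/activities[at0001]/description[at0002]/items[at0003]",
        "/activities[at0001]/description[at0002]/items[at0007]")))))
  back <- read_case(text = write_case(case))
  expect_true(case_equal(case, back))
  vals <- get_value(back, img,
                    "/activities[at0001]/description[at0002]/items[at0003]")
  expect_equal(vals[[1]]$code, "50960005")
  expect_equal(vals[[1]]$display, "Haemorrhage")
})

test_that("case serialization round-trips for generated cases in both formats", {
  for (i in c(1, 5, 9, 23, 27)) {
    case <- random_generated_case(i)
    expect_true(case_equal(case, read_case(text = write_case(case))),
                info = paste("dadl", i))
    expect_true(case_equal(case, read_case_json(text = write_case_json(case))),
                info = paste("json", i))
  }
  empty <- patient_case("empty", "2014-01-01T00:00:00Z")
  expect_true(case_equal(empty, read_case(text = write_case(empty))))
})

test_that("truncated case files fail with a positioned parse error", {
  txt <- write_case(random_generated_case(2))
  lines <- strsplit(txt, "\n")[[1]]
  truncated <- paste(lines[1:25], collapse = "\n")
  expect_error(read_case(text = truncated), "line")
})

test_that("validated cases are fully addressable through get_value", {
  for (i in c(3, 11, 30)) {
    case <- random_generated_case(i)
    expect_equal(nrow(validate_case(case, REG)), 0L)
    for (e in case$entries) {
      schema <- get_schema(REG, e$archetype_id)
      for (p in names(e$elements)) {
        vals <- get_value(case, e$archetype_id, p)
        expect_true(length(vals) >= 1L)
        kinds <- unique(vapply(vals, dv_kind, character(1)))
        expect_equal(kinds, schema$elements[[p]]$kind)
      }
    }
  }
})
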