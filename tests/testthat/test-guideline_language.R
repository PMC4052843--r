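test_that("condition expressions parse to the expected ASTs", {
  ast <- parse_expression("$gt0008>25")
  expect_equal(ast$node, "comparison")
  expect_equal(ast$op, ">")
  expect_equal(ast$lhs, list(node = "gt_ref", code = "gt0008"))
  expect_equal(ast$rhs$value, 25)

  isa <- parse_expression("$gt0003 is_a local::gt0102|stroke|")
  expect_equal(isa$node, "is_a")
  expect_equal(isa$group, "gt0102")
  expect_equal(isa$display, "stroke")

  tw <- parse_expression("$gt0004+PT4H30M<currentDateTime")
  expect_equal(tw$node, "comparison")
  expect_equal(tw$lhs$node, "arith")
  expect_equal(tw$lhs$rhs$value, "PT4H30M")
  expect_equal(tw$rhs$node, "current_datetime")

  disj <- parse_expression("$gt0010<3 || $gt0010>22")
  expect_equal(disj$node, "or")
  expect_length(disj$args, 2L)

  guard <- parse_expression("!exists($gt9001)")
  expect_equal(guard$node, "not")
  expect_equal(guard$x, list(node = "exists", code = "gt9001"))
})

test_that("action expressions parse assignments and reject them in conditions", {
  a <- parse_expression("$gt0016=true", role = "then")
  expect_equal(a$node, "assign")
  expect_equal(a$target, "gt0016")
  expect_true(a$value$value)

  coded <- parse_expression("$gt9106=local::at0006|Nasal canula|", role = "then")
  expect_equal(coded$value$code, "at0006")

  sum_rule <- parse_expression("$gt2100=$gt2001+$gt2002+$gt2003", role = "then")
  expect_equal(sum_rule$value$node, "arith")

  expect_error(parse_expression("$gt0016=true"), "assignment")
  expect_error(parse_expression("$gt0008>"), "syntax error")
  expect_error(parse_expression("$gt0008 >> 25"), "syntax error")
})

test_that("every string either parses or raises a positioned error", {
  set.seed(4321)
  alphabet <- c(LETTERS, letters, 0:9, "$", ">", "<", "=", "!", "|", "&",
                "(", ")", "+", "-", ".", ":", "\"", " ")
  for (i in 1:300) {
    txt <- paste(sample(alphabet, sample(1:25, 1), replace = TRUE),
                 collapse = "")
    out <- tryCatch(parse_expression(txt), error = function(e) e)
    if (inherits(out, "error")) {
      expect_match(conditionMessage(out), "column|syntax", info = txt)
    } else {
      expect_true(is.list(out) && !is.null(out$node), info = txt)
    }
  }
})

test_that("deparse followed by parse is the identity on shipped rules", {
  for (g in GUIDELINES) {
    for (r in g$rules) {
      for (w in r$when) {
        expect_equal(parse_expression(deparse_expr(w)), w,
                     info = paste(g$guideline_id, r$rule_id))
      }
      for (a in r$then) {
        expect_equal(parse_expression(deparse_expr(a), role = "then"), a,
                     info = paste(g$guideline_id, r$rule_id))
      }
    }
  }
})

test_that("shipped guideline files round-trip structurally", {
  dir <- system.file("extdata", "guidelines", package = "strokecds")
  builders <- list(
    thrombolysis_contraindications = build_thrombolysis_guideline,
    nihss_score = build_nihss_guideline,
    euro_compliance_criteria = build_euro_criteria_guideline)
  for (f in list.files(dir, full.names = TRUE)) {
    parsed <- parse_guideline(f)
    built <- builders[[sub("\\.gdl$", "", basename(f))]]()
    expect_true(guideline_equal(parsed, built), info = basename(f))
    reparsed <- parse_guideline(text = serialize_guideline(parsed))
    expect_true(guideline_equal(parsed, reparsed), info = basename(f))
  }
})

test_that("guideline validation flags broken references", {
  bad_ref <- new_guideline("g1", bindings = list(
    gdl_binding("gt0001", "openEHR-EHR-OBSERVATION.exam",
                "/data[at0001]/items[at0003]", "input"),
    gdl_binding("gt9001", "openEHR-EHR-EVALUATION.alert",
                "/data[at0001]/items[at0010]", "output")),
    rules = list(gdl_rule("r1", "$gt9999>1", "$gt9001=true")))
  v <- validate_guideline(bad_ref, REG, STORE)
  expect_true("unbound_gt_code" %in% v$problem)

  bad_path <- new_guideline("g2", bindings = list(
    gdl_binding("gt0001", "openEHR-EHR-OBSERVATION.exam",
                "/data[at0001]/items[at9876]", "input")))
  expect_true("unknown_path" %in% validate_guideline(bad_path, REG, STORE)$problem)

  no_codes <- new_guideline("g3",
    bindings = list(
      gdl_binding("gt0001", "openEHR-EHR-OBSERVATION.exam",
                  "/data[at0001]/items[at0003]", "input"),
      gdl_binding("gt9001", "openEHR-EHR-EVALUATION.alert",
                  "/data[at0001]/items[at0010]", "output")),
    term_groups = list(term_group("gt0102", "ghost",
                                  list("SNOMED-CT" = "000000"))),
    rules = list(gdl_rule("r1", "$gt0001 is_a local::gt0102|ghost|",
                          "$gt9001=true")))
  expect_true("unknown_code" %in% validate_guideline(no_codes, REG, STORE)$problem)

  mismatch <- new_guideline("g4", bindings = list(
    gdl_binding("gt0001", "openEHR-EHR-OBSERVATION.exam",
                "/data[at0001]/items[at0003]", "input"),
    gdl_binding("gt9001", "openEHR-EHR-EVALUATION.alert",
                "/data[at0001]/items[at0010]", "output")),
    rules = list(gdl_rule("r1", "$gt0001>5", "$gt9001=true")))
  expect_true("type_mismatch" %in% validate_guideline(mismatch, REG, STORE)$problem)

  empty_rules <- new_guideline("g5", bindings = list(
    gdl_binding("gt0001", "openEHR-EHR-OBSERVATION.exam",
                "/data[at0001]/items[at0003]", "input")))
  expect_equal(nrow(validate_guideline(empty_rules, REG, STORE)), 0L)
})

test_that("rule and guideline constructors enforce structural invariants", {
  expect_error(gdl_rule("r1", "$gt0001>1", character()), "empty then")
  expect_error(new_guideline("g", rules = list(
    gdl_rule("r1", then = "$gt0001=true"),
    gdl_rule("r1", then = "$gt0001=false"))), "duplicate rule id")
  expect_error(new_guideline("g", bindings = list(
    gdl_binding("gt0001", "a.b", "/data[at0001]", "input"),
    gdl_binding("gt0001", "a.b", "/data[at0002]", "input"))),
    "duplicate gt-code")
})
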