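test_that("is_a is reflexive and follows transitive parent links", {
  expect_true(is_a(STORE, "SNOMED-CT", "230690007", "230690007"))
  expect_true(is_a(STORE, "SNOMED-CT", "422504002", "230690007"))
  expect_true(is_a(STORE, "ATC", "B01AA03", "B01A"))
  expect_false(is_a(STORE, "SNOMED-CT", "50960005", "230690007"))
  expect_error(is_a(STORE, "SNOMED-CT", "999999", "230690007"), "unknown code")
  # three-level toy chain
  toy <- terminology_store(list(code_system(
    "TOY", c(a = "A", b = "B", c = "C"), list(b = "a", c = "b"))))
  expect_true(is_a(toy, "TOY", "c", "a"))
  expect_false(is_a(toy, "TOY", "a", "c"))
})

test_that("is_a agrees with brute-force reachability on random DAGs", {
  set.seed(1234)
  for (rep in 1:8) {
    dag <- random_dag_system(sample(10:50, 1))
    store <- terminology_store(list(dag$system))
    pairs <- expand.grid(from = dag$codes, to = dag$codes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[sample.int(nrow(pairs), min(200, nrow(pairs))), ]
    for (i in seq_len(nrow(pairs))) {
      expect_identical(
        is_a(store, "TOY", pairs$from[i], pairs$to[i]),
        reachable_bruteforce(dag$parents, pairs$from[i], pairs$to[i]),
        info = paste(rep, pairs$from[i], pairs$to[i]))
    }
  }
})

test_that("matches_group respects multi-system bindings and subsumption", {
  stroke <- term_group("gt0102", "stroke",
                       list("ICD10" = "I64", "SNOMED-CT" = "230690007"))
  expect_true(matches_group(dv_coded("ICD10", "I64", "Stroke"), stroke, STORE))
  expect_true(matches_group(dv_coded("SNOMED-CT", "422504002", ""),
                            stroke, STORE))  # via the hierarchy
  expect_false(matches_group(dv_coded("ATC", "B01AA03", ""), stroke, STORE))
  postictal <- term_group("gt0105", "postictal paresis",
                          list("SNOMED-CT" = "66264000", "ICD10" = "G83.8"))
  expect_true(matches_group(dv_coded("SNOMED-CT", "66264000", ""),
                            postictal, STORE))
  expect_true(matches_group(dv_coded("ICD10", "G83.8", ""), postictal, STORE))
})

test_that("matches_group is monotone in the group's code sets", {
  set.seed(99)
  dag <- random_dag_system(30)
  store <- terminology_store(list(dag$system))
  for (rep in 1:20) {
    base_codes <- sample(dag$codes, 3)
    grown_codes <- unique(c(base_codes, sample(dag$codes, 2)))
    value <- dv_coded("TOY", sample(dag$codes, 1), "")
    base <- term_group("g1", "g", list(TOY = base_codes))
    grown <- term_group("g1", "g", list(TOY = grown_codes))
    if (matches_group(value, base, store)) {
      expect_true(matches_group(value, grown, store))
    }
  }
})

test_that("the shipped tables load with the anchor codes present", {
  expect_true(all(c("230690007", "66264000", "50960005", "12738006") %in%
                    names(STORE$systems[["SNOMED-CT"]]$concepts)))
  expect_true(all(c("I64", "G83.8") %in% names(STORE$systems$ICD10$concepts)))
  expect_true(is_a(STORE, "ICD10", "G83.8", "G83"))
})

test_that("degenerate terminology configurations are rejected or inert", {
  empty <- terminology_store(list(code_system("EMPTY")))
  expect_error(is_a(empty, "EMPTY", "x", "x"), "unknown code")
  expect_error(code_system("CYC", c(a = "A", b = "B"),
                           list(a = "b", b = "a")), "cycle")
  expect_error(code_system("DANGLE", c(a = "A"), list(a = "zz")), "dangling")
  tmp <- tempfile(fileext = ".tsv")
  writeLines("code\tdisplay\tparents\na\tA\tb\nb\tB\ta", tmp)
  expect_error(load_terminology(tmp), "cycle")
})
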