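# Shared fixtures, built once per test run. All fixtures are constructed in
# code; nothing is read from outside the installed package.

REG <- stroke_schema_registry()
STORE <- stroke_terminology()
GUIDELINES <- stroke_guidelines()
PROBE_CONTENT <- list(guidelines = GUIDELINES, registry = REG, store = STORE)

# A case holding only an NIHSS observation with the given item levels.
nihss_case <- function(levels, case_id = "nihss_case") {
  items <- nihss_items()
  stopifnot(length(levels) == nrow(items), all(levels <= items$max_score))
  els <- list()
  for (k in items$item) {
    els[[items$path[k]]] <- dv_coded("local",
                                     sprintf("at2%02d%d", k, levels[k]),
                                     paste0(items$name[k], ", score ",
                                            levels[k]))
  }
  patient_case(case_id, "2014-06-01T12:00:00Z",
               list(new_entry("openEHR-EHR-OBSERVATION.nihss",
                              "2014-06-01T11:00:00Z", els)))
}

# Engine-derived NIHSS total for an item-level vector.
engine_nihss_total <- function(levels) {
  res <- run_guideline(GUIDELINES$nihss, nihss_case(levels), REG, STORE)
  v <- res$outputs[["gt2100"]]
  if (is.null(v)) NA_integer_ else v$value
}

# A random valid ISO-ish patient case via the cohort generator.
random_generated_case <- function(i) {
  profiles <- scenario_profiles()$profile_id
  generate_case(profiles[(i - 1L) %% length(profiles) + 1L],
                seed = 70000 + i, case_id = paste0("fuzz_", i))
}

# Brute-force reachability on a parent map (the oracle for is_a).
reachable_bruteforce <- function(parents, from, to) {
  if (from == to) return(TRUE)
  stack <- from
  seen <- character()
  while (length(stack)) {
    cur <- stack[[1]]
    stack <- stack[-1]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    for (p in parents[[cur]]) {
      if (p == to) return(TRUE)
      stack <- c(stack, p)
    }
  }
  FALSE
}

# Random DAG code system: codes c1..cn, parents only towards lower indices.
random_dag_system <- function(n, p_edge = 0.15) {
  codes <- paste0("c", seq_len(n))
  parents <- list()
  for (i in seq_len(n)) {
    if (i == 1L) next
    cand <- codes[seq_len(i - 1L)]
    pick <- cand[stats::runif(length(cand)) < p_edge]
    if (length(pick)) parents[[codes[i]]] <- pick
  }
  list(system = code_system("TOY", stats::setNames(codes, codes), parents),
       parents = parents, codes = codes)
}
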