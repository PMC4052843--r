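#' Retrospective compliance auditing
#'
#' The audit runs the shipped guidelines over a cohort and reports, per case
#' and per criterion, one of three verdicts: `triggered` (the criterion's
#' conditions are met), `not_triggered` (the case holds enough data to
#' exclude it), or `indeterminate` (the record is too incomplete to decide
#' either way — never silently treated as compliant). Cohort-level counts
#' and an overall non-compliance tally (thrombolytic given despite at least
#' one triggered contraindication) summarise the result.
#'
#' [oracle_check()] is the validation yardstick: a straight-line,
#' engine-free re-implementation of every criterion directly over the case's
#' entries, playing the role a manual chart review plays for the engine. The
#' headline property of the package is that engine and oracle verdict
#' vectors agree on every generated case.
#'
#' @name compliance
NULL

VERDICT_LEVELS <- c("triggered", "not_triggered", "indeterminate")

verdict_of_flag <- function(v) {
  if (isTRUE(v)) "triggered" else if (isFALSE(v)) "not_triggered" else "indeterminate"
}

# Does the case hold a diagnosis entry with a stroke code and an onset?
# Used by the audit-level temperature-monitoring mapping (absence of
# temperature observations means "not monitored", provided the monitoring
# window is anchored by a known stroke onset).
stroke_onset_known <- function(case, store) {
  for (e in entries_of(case, sk$diagnosis)) {
    code <- e$elements[[sk$p_diag]]
    onset <- e$elements[[sk$p_onset]]
    if (is.null(code) || is.null(onset)) next
    hit <- tryCatch(
      matches_group(code, term_group("g", "stroke",
                                     list("ICD10" = "I64",
                                          "SNOMED-CT" = "230690007")), store),
      error = function(e) FALSE)
    if (hit) return(TRUE)
  }
  FALSE
}

#' Engine verdicts for one case
#'
#' Runs the thrombolysis-contraindication and European-criteria guidelines
#' and maps their outputs onto the per-criterion verdict vector (14
#' contraindication rows plus 5 European rows).
#'
#' @param case A [patient_case()].
#' @param guidelines Named list as from [stroke_guidelines()].
#' @param registry,store Schema registry and terminology store.
#' @return Tibble `criterion_id`, `status`.
#' @export
engine_verdicts <- function(case, guidelines = stroke_guidelines(),
                            registry = stroke_schema_registry(),
                            store = stroke_terminology()) {
  contra <- run_guideline(guidelines$thrombolysis, case, registry, store)
  euro <- run_guideline(guidelines$euro, case, registry, store)
  cs <- criterion_specs()
  rep <- cs[cs$represented, ]
  rows <- lapply(seq_len(nrow(rep)), function(i) {
    tibble::tibble(criterion_id = rep$criterion_id[i],
                   status = verdict_of_flag(flag_value(contra, rep$flag_gt[i])))
  })
  monit <- flag_value(euro, "gt9103")
  if (is.na(monit) && stroke_onset_known(case, store)) monit <- FALSE
  oxy <- if (!is.null(euro$outputs[["gt9105"]])) "triggered"
    else if ("gt9105" %in% euro$determinate_unset) "not_triggered"
    else "indeterminate"
  rows <- c(rows, list(tibble::tibble(
    criterion_id = euro_criterion_specs()$criterion_id,
    status = c(verdict_of_flag(flag_value(euro, "gt9101")),
               verdict_of_flag(flag_value(euro, "gt9102")),
               verdict_of_flag(monit),
               verdict_of_flag(flag_value(euro, "gt9104")),
               oxy))))
  dplyr::bind_rows(rows)
}

#' Was a thrombolytic administered?
#'
#' Scans intravenous-fluid administrations for a fibrinolytic ATC code
#' (B01AD subtree).
#'
#' @inheritParams engine_verdicts
#' @return `TRUE` or `FALSE`.
#' @export
thrombolysis_given <- function(case, store = stroke_terminology()) {
  for (e in entries_of(case, sk$ivf)) {
    code <- e$elements[[sk$p_fluid]]
    if (is.null(code) || code$system != "ATC") next
    hit <- tryCatch(is_a(store, "ATC", code$code, "B01AD"),
                    error = function(err) FALSE)
    if (hit) return(TRUE)
  }
  FALSE
}

# ---------------------------------------------------------------------------
# The brute-force oracle: each criterion re-derived straight from the
# entries with local three-valued helpers. No guideline objects, no
# expression parsing, no working memory, no subsumption queries - ancestor
# chains are walked directly on the terminology tables.
# ---------------------------------------------------------------------------

orc_reaches <- function(sys, code, roots) {
  if (!code %in% names(sys$concepts)) return(FALSE)
  frontier <- code
  seen <- character()
  while (length(frontier)) {
    if (any(frontier %in% roots)) return(TRUE)
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(sys$parents[frontier], use.names = FALSE)),
                        seen)
  }
  FALSE
}

# Three-valued group membership: NA when the value is absent.
orc_in <- function(dv, groupdef, store) {
  if (is.null(dv)) return(NA)
  roots <- groupdef[[dv$system]]
  if (is.null(roots)) return(FALSE)
  sys <- store$systems[[dv$system]]
  if (is.null(sys)) return(FALSE)
  orc_reaches(sys, dv$code, roots)
}

orc_and <- function(...) k_and(list(...))

# Code sets as the oracle understands the criteria (deliberately restated
# rather than shared with the guideline content).
oracle_groups <- function() {
  list(
    stroke = list("ICD10" = "I64", "SNOMED-CT" = "230690007"),
    ich = list("ICD10" = c("I61", "I62"),
               "SNOMED-CT" = c("274100004", "1386000")),
    headache = list("SNOMED-CT" = "21794005"),
    postictal = list("SNOMED-CT" = "66264000", "ICD10" = "G83.8"),
    septic = list("SNOMED-CT" = "76571007", "ICD10" = "R57.2"),
    bleed_dx = list("SNOMED-CT" = "64779008", "ICD10" = "D68"),
    anticoag = list("ATC" = c("B01AA", "B01AB", "B01AF")),
    comorbid = list("SNOMED-CT" = c("61420007", "3238004", "111293003",
                                    "253416000", "84114007", "75694006",
                                    "235856003"),
                    "ICD10" = c("I33", "I30", "I51.3", "I50", "K85", "K72")),
    week_proc = list("SNOMED-CT" = c("45036003", "392247006")),
    month_dx = list("SNOMED-CT" = c("283545005", "51868009", "34436003"),
                    "ICD10" = c("S36", "K26", "R31")),
    month_proc = list("SNOMED-CT" = c("86273004", "112746006")),
    m3_dx = list("SNOMED-CT" = c("82271004", "74474003"),
                 "ICD10" = c("S09", "K92.2")),
    cns_proc = list("SNOMED-CT" = "25353009"),
    preg = list("SNOMED-CT" = c("77386006", "169750002"),
                "ICD10" = c("Z33", "Z39.1")),
    birth = list("SNOMED-CT" = "386216000", "ICD10" = "O80"),
    haem_finding = list("SNOMED-CT" = "50960005"),
    brain_site = list("SNOMED-CT" = "12738006"),
    exam_mri = list("SNOMED-CT" = c("95460007", "472916000")),
    mimic = list("SNOMED-CT" = "709491003"),
    deficit = list("SNOMED-CT" = "432504007")
  )
}

# triggered / not_triggered / indeterminate from per-tuple evaluations of
# the criterion condition and its explicit exclusion condition.
orc_status <- function(true_vals, false_vals) {
  if (any(vapply(true_vals, isTRUE, logical(1)))) return("triggered")
  if (any(vapply(false_vals, isTRUE, logical(1)))) return("not_triggered")
  "indeterminate"
}

# One-sided criteria: no exclusion rule; determinately untriggered only when
# every relevant entry pool is populated and no evaluation was unknown.
orc_status_oneside <- function(eval_groups) {
  vals <- unlist(eval_groups)
  if (any(vapply(vals, isTRUE, logical(1)))) return("triggered")
  if (any(!lengths(eval_groups))) return("indeterminate")
  if (any(is.na(vals))) return("indeterminate")
  "not_triggered"
}

#' Brute-force oracle verdicts for one case
#'
#' @inheritParams engine_verdicts
#' @return Tibble `criterion_id`, `status` with the same 19 rows as
#'   [engine_verdicts()].
#' @export
oracle_check <- function(case, store = stroke_terminology()) {
  G <- oracle_groups()
  now <- as.numeric(case$reference_time)
  H <- 3600

  diags <- entries_of(case, sk$diagnosis)
  dx <- lapply(diags, function(e) list(
    code = e$elements[[sk$p_diag]],
    onset = e$elements[[sk$p_onset]]))
  onset_num <- function(d) if (is.null(d$onset)) NA_real_ else as.numeric(d$onset$value)
  procs <- lapply(entries_of(case, sk$procedure), function(e) list(
    code = e$elements[[sk$p_proc]],
    time = e$elements[[sk$p_proc_time]]))
  ptime <- function(p) if (is.null(p$time)) NA_real_ else as.numeric(p$time$value)
  meds <- lapply(entries_of(case, sk$medication), function(e)
    e$elements[[sk$p_med]])
  imgs <- lapply(entries_of(case, sk$imaging), function(e) list(
    findings = e$elements[[sk$p_img_findings]],
    site = e$elements[[sk$p_img_site]]))
  exams <- lapply(entries_of(case, sk$exam), function(e) e$elements[[sk$p_exam]])
  temps <- lapply(entries_of(case, sk$temp), function(e) list(
    val = e$elements[[sk$p_temp]],
    time = e$elements[[sk$p_temp_time]]))
  spo2s <- lapply(entries_of(case, sk$oximetry), function(e)
    e$elements[[sk$p_spo2]])
  nihss_totals <- get_value(case, sk$nihss, sk$p_nihss_total)
  glucoses <- get_value(case, sk$glucose, sk$p_glucose)

  cmp_na <- function(x) if (length(x) && !is.na(x)) x else NA

  # c01: stroke onset more than 4.5 hours before the decision
  t01 <- lapply(dx, function(d) orc_and(orc_in(d$code, G$stroke, store),
                                        cmp_na(onset_num(d) + 4.5 * H < now)))
  f01 <- lapply(dx, function(d) orc_and(orc_in(d$code, G$stroke, store),
                                        cmp_na(onset_num(d) + 4.5 * H >= now)))
  s01 <- orc_status(t01, f01)

  # c02: NIHSS total above 25
  t02 <- lapply(nihss_totals, function(v) v$value > 25)
  s02 <- orc_status(t02, lapply(nihss_totals, function(v) v$value <= 25))

  # c03: imaging shows haemorrhage in the brain
  t03 <- lapply(imgs, function(i) orc_and(orc_in(i$findings, G$haem_finding, store),
                                          orc_in(i$site, G$brain_site, store)))
  s03 <- orc_status(t03, lapply(t03, k_not))

  # c04: glucose below 3 or above 22 mmol/L
  t04 <- lapply(glucoses, function(v) v$magnitude < 3 || v$magnitude > 22)
  s04 <- orc_status(t04, lapply(t04, k_not))

  # simple any-time diagnosis-group criteria
  dx_criterion <- function(group) {
    tv <- lapply(dx, function(d) orc_in(d$code, group, store))
    orc_status(tv, lapply(tv, k_not))
  }
  s05 <- dx_criterion(G$ich)
  s06 <- dx_criterion(G$headache)
  s07 <- dx_criterion(G$postictal)
  s08 <- dx_criterion(G$septic)
  s10 <- dx_criterion(G$comorbid)

  # c09: bleeding disorder diagnosis or anticoagulant on the medication list
  t09a <- lapply(dx, function(d) orc_in(d$code, G$bleed_dx, store))
  t09b <- lapply(meds, function(m) orc_in(m, G$anticoag, store))
  f09 <- list()
  for (d in dx) for (m in meds) {
    f09[[length(f09) + 1L]] <- orc_and(k_not(orc_in(d$code, G$bleed_dx, store)),
                                       k_not(orc_in(m, G$anticoag, store)))
  }
  s09 <- orc_status(c(t09a, t09b), f09)

  # c11: lumbar puncture or central venous catheter in the last week
  t11 <- lapply(procs, function(p) orc_and(orc_in(p$code, G$week_proc, store),
                                           cmp_na(ptime(p) + 168 * H > now)))
  s11 <- orc_status(t11, lapply(t11, k_not))

  # c12: organ operation/biopsy, internal trauma, ulcer or urinary bleeding
  # in the last month (diagnosis or procedure route)
  c12_dx <- function(d) orc_and(orc_in(d$code, G$month_dx, store),
                                cmp_na(onset_num(d) + 720 * H > now))
  c12_proc <- function(p) orc_and(orc_in(p$code, G$month_proc, store),
                                  cmp_na(ptime(p) + 720 * H > now))
  f12 <- list()
  for (d in dx) for (p in procs) {
    f12[[length(f12) + 1L]] <- orc_and(k_not(c12_dx(d)), k_not(c12_proc(p)))
  }
  s12 <- orc_status(c(lapply(dx, c12_dx), lapply(procs, c12_proc)), f12)

  # c13: stroke, head trauma, CNS operation or GI bleeding in the last three
  # months; the index stroke (within 24 h of the decision) does not count
  c13_stroke <- function(d) orc_and(orc_in(d$code, G$stroke, store),
                                    cmp_na(onset_num(d) + 2160 * H > now),
                                    cmp_na(onset_num(d) + 24 * H < now))
  c13_dx <- function(d) orc_and(orc_in(d$code, G$m3_dx, store),
                                cmp_na(onset_num(d) + 2160 * H > now))
  c13_proc <- function(p) orc_and(orc_in(p$code, G$cns_proc, store),
                                  cmp_na(ptime(p) + 2160 * H > now))
  f13 <- list()
  for (d in dx) for (p in procs) {
    f13[[length(f13) + 1L]] <- orc_and(k_not(c13_stroke(d)), k_not(c13_dx(d)),
                                       k_not(c13_proc(p)))
  }
  s13 <- orc_status(c(lapply(dx, c13_stroke), lapply(dx, c13_dx),
                      lapply(procs, c13_proc)), f13)

  # c14: pregnancy, childbirth within a month, breastfeeding
  c14_preg <- function(d) orc_in(d$code, G$preg, store)
  c14_birth <- function(d) orc_and(orc_in(d$code, G$birth, store),
                                   cmp_na(onset_num(d) + 720 * H > now))
  f14 <- lapply(dx, function(d) orc_and(k_not(c14_preg(d)), k_not(c14_birth(d))))
  s14 <- orc_status(c(lapply(dx, c14_preg), lapply(dx, c14_birth)), f14)

  # European criteria -------------------------------------------------------
  e_mri <- orc_status_oneside(list(
    lapply(exams, function(x) orc_in(x, G$exam_mri, store)),
    lapply(imgs, function(i) orc_in(i$findings, G$mimic, store))))
  lys <- list()
  for (x in exams) for (d in dx) {
    lys[[length(lys) + 1L]] <- orc_and(orc_in(x, G$deficit, store),
                                       orc_in(d$code, G$stroke, store),
                                       cmp_na(onset_num(d) + 4.5 * H > now))
  }
  e_lys <- orc_status_oneside(list(lys))

  stroke_onsets <- Filter(Negate(is.na), vapply(dx, function(d) {
    if (isTRUE(orc_in(d$code, G$stroke, store)) && !is.null(d$onset)) {
      onset_num(d)
    } else NA_real_
  }, numeric(1)))
  in_window <- function(tm, onset) !is.na(tm) && tm >= onset && tm < onset + 72 * H
  mon <- list()
  pyr <- list()
  for (tp in temps) for (d in dx) {
    tm <- if (is.null(tp$time)) NA_real_ else as.numeric(tp$time$value)
    win <- orc_and(orc_in(d$code, G$stroke, store),
                   cmp_na(tm >= onset_num(d)),
                   cmp_na(tm < onset_num(d) + 72 * H))
    mon[[length(mon) + 1L]] <- win
    pyr[[length(pyr) + 1L]] <- orc_and(win,
                                       if (is.null(tp$val)) NA else tp$val$magnitude > 37.5)
  }
  e_mon <- orc_status_oneside(list(mon))
  if (e_mon == "indeterminate" && length(stroke_onsets)) e_mon <- "not_triggered"
  e_pyr <- orc_status_oneside(list(pyr))
  e_oxy <- orc_status_oneside(list(lapply(spo2s, function(v) v$magnitude < 95)))

  cs <- criterion_specs()
  tibble::tibble(
    criterion_id = c(cs$criterion_id[cs$represented],
                     euro_criterion_specs()$criterion_id),
    status = c(s01, s02, s03, s04, s05, s06, s07, s08, s09, s10, s11, s12,
               s13, s14, e_mri, e_lys, e_mon, e_pyr, e_oxy))
}

#' Audit a cohort
#'
#' Runs [engine_verdicts()] on every case, aggregates per-criterion counts
#' and tallies overall non-compliance (a thrombolytic administered despite
#' at least one triggered contraindication). Cases may be given as a list of
#' case objects or as a directory of case files; unreadable files are
#' recorded and skipped.
#'
#' @param cases List of [patient_case()]s, or a directory path.
#' @inheritParams engine_verdicts
#' @return A `strokecds_report`: list with `verdicts` (long tibble),
#'   `criterion_counts` (wide tibble), `case_summary`,
#'   `non_compliance_count`, `n_cases` and `case_errors`.
#' @export
audit <- function(cases, guidelines = stroke_guidelines(),
                  registry = stroke_schema_registry(),
                  store = stroke_terminology()) {
  errors <- tibble::tibble(file = character(), error = character())
  if (is.character(cases) && length(cases) == 1L) {
    loaded <- read_cohort(cases)
    errors <- loaded$errors
    cases <- loaded$cases
  }
  ids <- vapply(cases, `[[`, character(1), "case_id")
  if (anyDuplicated(ids)) stop("duplicate case ids in cohort", call. = FALSE)
  verdicts <- dplyr::bind_rows(lapply(cases, function(case) {
    dplyr::mutate(engine_verdicts(case, guidelines, registry, store),
                  case_id = case$case_id, .before = 1)
  }))
  contra_ids <- criterion_specs()$criterion_id[criterion_specs()$represented]
  lysis <- vapply(cases, thrombolysis_given, logical(1), store = store)
  names(lysis) <- ids
  case_summary <- if (nrow(verdicts)) {
    verdicts |>
      dplyr::group_by(.data$case_id) |>
      dplyr::summarise(
        n_triggered = sum(.data$status == "triggered" &
                            .data$criterion_id %in% contra_ids),
        n_indeterminate = sum(.data$status == "indeterminate"),
        .groups = "drop") |>
      dplyr::mutate(thrombolysis_given = unname(lysis[.data$case_id]),
                    non_compliant = .data$thrombolysis_given &
                      .data$n_triggered > 0L)
  } else {
    tibble::tibble(case_id = character(), n_triggered = integer(),
                   n_indeterminate = integer(), thrombolysis_given = logical(),
                   non_compliant = logical())
  }
  counts <- if (nrow(verdicts)) {
    verdicts |>
      dplyr::count(.data$criterion_id, .data$status) |>
      tidyr::pivot_wider(names_from = "status", values_from = "n",
                         values_fill = 0L)
  } else {
    tibble::tibble(criterion_id = character())
  }
  for (lvl in VERDICT_LEVELS) {
    if (!lvl %in% names(counts)) counts[[lvl]] <- 0L
  }
  structure(list(
    verdicts = verdicts,
    criterion_counts = counts[, c("criterion_id", VERDICT_LEVELS)],
    case_summary = case_summary,
    non_compliance_count = sum(case_summary$non_compliant),
    n_cases = length(cases),
    case_errors = errors),
    class = "strokecds_report")
}

#' @export
print.strokecds_report <- function(x, ...) {
  cat("<compliance report> ", x$n_cases, " cases, ",
      x$non_compliance_count,
      " non-compliant (thrombolysis despite contraindication)\n", sep = "")
  print(x$criterion_counts, n = Inf)
  invisible(x)
}

#' Compare engine and oracle verdicts
#'
#' The concordance experiment: per case, the entire verdict vector must be
#' identical for the case to count as a match.
#'
#' @param engine,oracle Long verdict tibbles (`case_id`, `criterion_id`,
#'   `status`) over the same cohort.
#' @return List with `n_cases`, `n_match`, `prop_match` and `discrepancies`
#'   (tibble of differing cells).
#' @export
compare_verdicts <- function(engine, oracle) {
  if (!setequal(unique(engine$case_id), unique(oracle$case_id))) {
    stop("engine and oracle cover different case ids", call. = FALSE)
  }
  joined <- dplyr::inner_join(engine, oracle,
                              by = c("case_id", "criterion_id"),
                              suffix = c("_engine", "_oracle"))
  if (nrow(joined) != nrow(engine) || nrow(joined) != nrow(oracle)) {
    stop("engine and oracle cover different criteria", call. = FALSE)
  }
  disc <- dplyr::filter(joined, .data$status_engine != .data$status_oracle)
  per_case <- dplyr::summarise(
    dplyr::group_by(joined, .data$case_id),
    match = all(.data$status_engine == .data$status_oracle), .groups = "drop")
  list(n_cases = nrow(per_case),
       n_match = sum(per_case$match),
       prop_match = mean(per_case$match),
       discrepancies = disc)
}

#' Run the audit and oracle over a cohort and compare them
#'
#' Convenience wrapper for the self-test mode: audits the cohort, runs the
#' oracle, and reports concordance.
#'
#' @inheritParams audit
#' @return List with `report`, `oracle` (long tibble) and `concordance`
#'   (from [compare_verdicts()]).
#' @export
audit_with_oracle <- function(cases, guidelines = stroke_guidelines(),
                              registry = stroke_schema_registry(),
                              store = stroke_terminology()) {
  report <- audit(cases, guidelines, registry, store)
  oracle <- dplyr::bind_rows(lapply(cases, function(case) {
    dplyr::mutate(oracle_check(case, store), case_id = case$case_id,
                  .before = 1)
  }))
  list(report = report, oracle = oracle,
       concordance = compare_verdicts(report$verdicts, oracle))
}

#' @rdname audit
#' @param x A `strokecds_report`.
#' @param ... Unused.
#' @method tidy strokecds_report
#' @export
tidy.strokecds_report <- function(x, ...) {
  x$verdicts
}

#' @rdname audit
#' @method glance strokecds_report
#' @export
glance.strokecds_report <- function(x, ...) {
  tibble::tibble(
    n_cases = x$n_cases,
    n_criteria = length(unique(x$verdicts$criterion_id)),
    n_triggered_cells = sum(x$verdicts$status == "triggered"),
    n_indeterminate_cells = sum(x$verdicts$status == "indeterminate"),
    non_compliance_count = x$non_compliance_count)
}

#' Plot per-criterion verdict counts
#'
#' @param object A `strokecds_report`.
#' @param ... Unused.
#' @return A ggplot: stacked horizontal bars of verdict counts per
#'   criterion, the cohort-statistics view of the audit.
#' @method autoplot strokecds_report
#' @export
autoplot.strokecds_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$criterion_counts, -"criterion_id",
                              names_to = "status", values_to = "n")
  long$status <- factor(long$status, levels = rev(VERDICT_LEVELS))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$criterion_id,
                                     fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(triggered = "#c0392b",
                                          not_triggered = "#7f8c8d",
                                          indeterminate = "#f1c40f")) +
    ggplot2::labs(x = "cases", y = NULL, fill = "verdict",
                  title = "Guideline criterion verdicts across the cohort") +
    ggplot2::theme_minimal()
}

#' @export
plot.strokecds_report <- function(x, ...) print(autoplot.strokecds_report(x, ...))
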