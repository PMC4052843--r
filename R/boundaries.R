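#' Black-box decision-boundary probing
#'
#' Utilities to recover the numeric decision boundaries of the shipped
#' content by construction: build an otherwise-clean single-feature case,
#' run the relevant guideline, and observe whether the flag (or
#' recommendation) fires. Combined with [recover_boundary()], this recovers
#' every numeric threshold in the content — NIHSS cut-off, onset window,
#' glucose bounds, SpO2 threshold, pyrexia temperature and the monitoring
#' window — without reading the rule text.
#'
#' @name boundary-probing
NULL

#' Bundle of content needed by the probes
#'
#' @return List with `guidelines`, `registry`, `store`; build once and pass
#'   to repeated [probe_flag()] calls.
#' @export
probe_content <- function() {
  list(guidelines = stroke_guidelines(),
       registry = stroke_schema_registry(),
       store = stroke_terminology())
}

#' Construct a minimal single-feature case
#'
#' The case holds a stroke diagnosis (with onset) plus exactly the entry the
#' probed feature needs, so that only one criterion's inputs vary.
#'
#' @param feature One of `"nihss_total"`, `"onset_hours"`, `"glucose"`,
#'   `"spo2"`, `"temperature"`, `"temp_offset_hours"`.
#' @param value The feature value: a score, hours from onset to the decision
#'   instant, mmol/L, %, degrees Celsius, or hours from onset to the
#'   temperature observation.
#' @return A [patient_case()].
#' @export
probe_case <- function(feature = c("nihss_total", "onset_hours", "glucose",
                                   "spo2", "temperature", "temp_offset_hours"),
                       value) {
  feature <- match.arg(feature)
  t0 <- parse_iso_datetime("2014-06-01T12:00:00Z")
  onset_h <- switch(feature,
    onset_hours = value,
    temperature = 100,
    temp_offset_hours = 100,
    2)
  onset <- t0 - onset_h * 3600
  entries <- list(new_entry(sk$diagnosis, onset + 600, stats::setNames(list(
    dv_coded("SNOMED-CT", "230690007", "Cerebrovascular accident"),
    dv_datetime(onset)), c(sk$p_diag, sk$p_onset))))
  extra <- switch(feature,
    nihss_total = new_entry(sk$nihss, t0 - 3600, stats::setNames(
      list(dv_count(as.integer(value))), sk$p_nihss_total)),
    glucose = new_entry(sk$glucose, t0 - 3600, stats::setNames(
      list(dv_quantity(value, "mmol/l")), sk$p_glucose)),
    spo2 = new_entry(sk$oximetry, t0 - 3600, stats::setNames(
      list(dv_quantity(value, "%")), sk$p_spo2)),
    temperature = {
      tt <- onset + 10 * 3600
      new_entry(sk$temp, tt, stats::setNames(
        list(dv_quantity(value, "\u00b0C"), dv_datetime(tt)),
        c(sk$p_temp, sk$p_temp_time)))
    },
    temp_offset_hours = {
      tt <- onset + value * 3600
      new_entry(sk$temp, tt, stats::setNames(
        list(dv_quantity(36.8, "\u00b0C"), dv_datetime(tt)),
        c(sk$p_temp, sk$p_temp_time)))
    },
    NULL)
  if (!is.null(extra)) entries <- c(entries, list(extra))
  patient_case(paste0("probe_", feature), t0, entries)
}

#' Evaluate the criterion a probed feature governs
#'
#' @param feature As in [probe_case()].
#' @param value The feature value.
#' @param content A [probe_content()] bundle.
#' @return `TRUE` if the governed flag (or the oxygen recommendation) is
#'   raised, `FALSE` if explicitly not, `NA` if indeterminate.
#' @export
probe_flag <- function(feature, value, content = probe_content()) {
  case <- probe_case(feature, value)
  if (feature %in% c("nihss_total", "onset_hours", "glucose")) {
    res <- run_guideline(content$guidelines$thrombolysis, case,
                         content$registry, content$store)
    gt <- switch(feature, onset_hours = "gt9001", nihss_total = "gt9002",
                 glucose = "gt9004")
    return(flag_value(res, gt))
  }
  res <- run_guideline(content$guidelines$euro, case,
                       content$registry, content$store)
  switch(feature,
    spo2 = !is.null(res$outputs[["gt9105"]]),
    temperature = isTRUE(flag_value(res, "gt9104")),
    temp_offset_hours = isTRUE(flag_value(res, "gt9103")))
}

#' Bisect a decision boundary
#'
#' Requires the predicate to differ between the interval ends; halves the
#' interval until it is narrower than `tol` and returns the midpoint.
#'
#' @param f Predicate: `function(x) TRUE/FALSE`.
#' @param lo,hi Interval ends.
#' @param tol Width at which to stop.
#' @return The transition estimate (interval midpoint at convergence).
#' @export
recover_boundary <- function(f, lo, hi, tol = 1e-3) {
  flo <- f(lo)
  fhi <- f(hi)
  if (identical(flo, fhi)) {
    stop("predicate does not change over [", lo, ", ", hi, "]", call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (identical(f(mid), flo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
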