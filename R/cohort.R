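#' Synthetic acute-stroke cohort generation
#'
#' Deterministic, seeded generation of mock acute-stroke patient cases for
#' retrospective compliance experiments. Every case is anchored at a
#' thrombolysis decision instant (the case's reference time) and carries a
#' full admission record: a coded stroke diagnosis with an onset timestamp, a
#' baseline chronic diagnosis, an NIHSS observation (item answers plus
#' total), blood glucose, blood pressure, body temperature series, oximetry,
#' a neurological examination, CT imaging findings, a medication order, a
#' procedure and an intravenous-fluid administration. Scenario profiles then
#' perturb single features so that each shipped criterion is triggered by
#' some cases and not by others.
#'
#' Value ranges are chosen to be clinically plausible rather than
#' distributionally realistic: glucose 2-25 mmol/L, SpO2 85-100%, NIHSS
#' 0-42, onset 0.5-12 h before the decision, and historic events 1-200 days
#' back.
#'
#' @name cohort
NULL

#' Scenario profiles
#'
#' @return Tibble with `profile_id`, `description` and `lysis_given`
#'   (whether the scenario administers thrombolytics, which combined with a
#'   triggered contraindication constitutes non-compliance).
#' @export
scenario_profiles <- function() {
  tibble::tribble(
    ~profile_id, ~lysis_given, ~description,
    "clean", TRUE, "uncomplicated ischaemic stroke within the treatment window",
    "onset_late", FALSE, "presentation more than 4.5 hours after onset",
    "nihss_high", FALSE, "severe deficit, NIHSS total above 25",
    "ct_haemorrhage", FALSE, "CT shows haemorrhage in the brain",
    "glucose_low", FALSE, "blood glucose below 3 mmol/L",
    "glucose_high", FALSE, "blood glucose above 22 mmol/L",
    "prior_ich", FALSE, "history of intracerebral haemorrhage",
    "explosive_headache", FALSE, "thunderclap headache at presentation",
    "postictal_paresis", FALSE, "likely postictal paresis",
    "septic_shock", FALSE, "suspected septic shock",
    "anticoagulated", TRUE, "ongoing warfarin treatment; thrombolysis given regardless",
    "bleeding_disorder", FALSE, "known coagulation disorder",
    "serious_comorbidity", FALSE, "cardiac, hepatic or pancreatic comorbidity",
    "recent_lp", FALSE, "lumbar puncture within the last week",
    "lp_8days", TRUE, "lumbar puncture eight days ago (outside the window)",
    "organ_biopsy_2w", FALSE, "parenchymatous organ biopsy two weeks ago",
    "duodenal_ulcer", FALSE, "active duodenal ulcer this month",
    "prior_stroke_80d", TRUE, "earlier stroke 30-85 days back; thrombolysis given regardless",
    "head_trauma_2m", FALSE, "head trauma within three months",
    "cns_operation_2m", FALSE, "central nervous system operation within three months",
    "pregnancy", FALSE, "ongoing pregnancy",
    "recent_childbirth", FALSE, "childbirth within the last month",
    "low_spo2_treated", TRUE, "SpO2 below 95% with oxygen given",
    "low_spo2_untreated", TRUE, "SpO2 below 95% without oxygen",
    "pyrexia", TRUE, "temperature above 37.5 Celsius in the monitoring window",
    "no_temp_monitoring", TRUE, "no body-temperature observations recorded",
    "mri_posterior", FALSE, "posterior circulation variety on examination",
    "stroke_mimic_ct", FALSE, "CT suspicious of a stroke mimic",
    "no_nihss", TRUE, "NIHSS never recorded",
    "no_glucose", TRUE, "blood glucose never measured"
  )
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate one synthetic case
#'
#' Deterministic in `(profile, seed)`: the same pair always yields the
#' field-for-field identical case.
#'
#' @param profile A `profile_id` from [scenario_profiles()].
#' @param seed Integer seed for this case.
#' @param case_id Case identifier; defaults to the profile name.
#' @return A schema-valid [patient_case()].
#' @export
generate_case <- function(profile, seed, case_id = profile) {
  profiles <- scenario_profiles()
  if (!profile %in% profiles$profile_id) {
    stop("unknown profile: ", profile, call. = FALSE)
  }
  with_seed(seed, build_case(profile, case_id,
                             profiles$lysis_given[profiles$profile_id == profile]))
}

hours <- function(h) h * 3600
days <- function(d) d * 86400

build_case <- function(profile, case_id, lysis_given) {
  items <- nihss_items()
  # decision instant: a random moment during 2014
  t0 <- parse_iso_datetime("2014-01-01T00:00:00Z") +
    floor(stats::runif(1, 0, 365)) * 86400 + floor(stats::runif(1, 0, 86400))
  onset_h <- if (profile == "onset_late") stats::runif(1, 5, 10)
    else stats::runif(1, 0.8, 4)
  onset <- t0 - hours(onset_h)
  admit <- onset + hours(stats::runif(1, 0.2, min(1, onset_h * 0.5)))

  entries <- list()
  add <- function(e) entries[[length(entries) + 1L]] <<- e
  # keep every recorded event at or before the decision instant
  before_t0 <- function(x) {
    as.POSIXct(pmin(as.numeric(x), as.numeric(t0) - 60),
               origin = "1970-01-01", tz = "UTC")
  }

  diag_entry <- function(system, code, display, onset_time, event_time,
                         confidence = "at0102") {
    new_entry(sk$diagnosis, event_time, stats::setNames(list(
      dv_coded(system, code, display),
      dv_datetime(onset_time),
      dv_coded("local", confidence,
               if (confidence == "at0101") "Suspicion" else "Certainty")),
      c(sk$p_diag, sk$p_onset, sk$p_confidence)))
  }
  proc_entry <- function(code, display, when) {
    new_entry(sk$procedure, when, stats::setNames(list(
      dv_coded("SNOMED-CT", code, display), dv_datetime(when)),
      c(sk$p_proc, sk$p_proc_time)))
  }

  # index stroke diagnosis (one of the coded stroke concepts)
  stroke_codes <- list(c("SNOMED-CT", "230690007", "Cerebrovascular accident"),
                       c("SNOMED-CT", "422504002", "Ischaemic stroke"),
                       c("ICD10", "I64", "Stroke"))
  scd <- stroke_codes[[sample.int(3, 1)]]
  add(diag_entry(scd[1], scd[2], scd[3], onset, admit))
  # baseline chronic diagnosis
  add(diag_entry("SNOMED-CT", "38341003", "Hypertension",
                 t0 - days(stats::runif(1, 400, 3000)),
                 t0 - days(stats::runif(1, 200, 399))))

  # NIHSS
  if (profile != "no_nihss") {
    levels <- if (profile == "nihss_high") {
      as.integer(items$max_score - stats::rbinom(nrow(items), 1, 0.3))
    } else {
      vapply(items$n_levels, function(n) {
        p <- c(0.62, 0.25, 0.13, 0.0, 0.0)[seq_len(n)]
        sample.int(n, 1, prob = p / sum(p)) - 1L
      }, integer(1))
    }
    els <- list()
    for (k in items$item) {
      els[[items$path[k]]] <- dv_coded("local", nihss_level_code(k, levels[k]),
                                       paste0(items$name[k], ", score ",
                                              levels[k]))
    }
    els[[sk$p_nihss_total]] <- dv_count(sum(levels))
    add(new_entry(sk$nihss, before_t0(admit + hours(stats::runif(1, 0.1, 0.4))), els))
  }

  # blood glucose
  if (profile != "no_glucose") {
    g <- switch(profile,
      glucose_low = stats::runif(1, 2.0, 2.8),
      glucose_high = stats::runif(1, 22.3, 25),
      stats::runif(1, 4.5, 7.5))
    add(new_entry(sk$glucose, before_t0(admit + hours(stats::runif(1, 0.1, 0.5))),
                  stats::setNames(list(dv_quantity(round(g, 1), "mmol/l")),
                                  sk$p_glucose)))
  }

  # blood pressure
  add(new_entry(sk$bp, before_t0(admit + hours(stats::runif(1, 0.05, 0.3))),
                stats::setNames(list(
                  dv_quantity(round(stats::runif(1, 120, 180)), "mmHg"),
                  dv_quantity(round(stats::runif(1, 70, 100)), "mmHg")),
                  c(sk$p_sys, sk$p_dia))))

  # body temperature series (within [onset, t0], hence inside the 72 h window)
  if (profile != "no_temp_monitoring") {
    n_obs <- if (profile == "pyrexia") 2L else sample(1:2, 1)
    for (j in seq_len(n_obs)) {
      tt <- onset + (t0 - onset) * stats::runif(1, 0.3, 0.95)
      temp <- if (profile == "pyrexia" && j == n_obs) {
        stats::runif(1, 37.7, 39.5)
      } else {
        stats::runif(1, 36.3, 37.2)
      }
      add(new_entry(sk$temp, tt, stats::setNames(list(
        dv_quantity(round(temp, 1), "\u00b0C"), dv_datetime(tt)),
        c(sk$p_temp, sk$p_temp_time))))
    }
  }

  # oximetry
  spo2 <- if (profile %in% c("low_spo2_treated", "low_spo2_untreated")) {
    stats::runif(1, 87, 93)
  } else {
    stats::runif(1, 96, 99.5)
  }
  spo2_time <- before_t0(admit + hours(stats::runif(1, 0.05, 0.3)))
  add(new_entry(sk$oximetry, spo2_time,
                stats::setNames(list(dv_quantity(round(spo2), "%")), sk$p_spo2)))
  if (profile == "low_spo2_treated") {
    gt <- before_t0(spo2_time + hours(stats::runif(1, 0.1, 0.5)))
    add(new_entry(sk$gas, gt, stats::setNames(list(
      dv_coded("SNOMED-CT", "24099007", "Oxygen"),
      dv_coded("local", "at0006", "Nasal canula"),
      dv_datetime(gt)),
      c(sk$p_gas, sk$p_gas_means, sk$p_gas_time))))
  }

  # neurological examination
  exam_code <- switch(profile,
    mri_posterior = c("95460007", "Posterior circulation stroke variety"),
    c("432504007", "Acute ischaemic neurological deficit"))
  add(new_entry(sk$exam, before_t0(admit + hours(stats::runif(1, 0.05, 0.4))),
                stats::setNames(list(dv_coded("SNOMED-CT", exam_code[1],
                                              exam_code[2])), sk$p_exam)))

  # CT imaging
  img <- switch(profile,
    ct_haemorrhage = c("50960005", "Haemorrhage"),
    stroke_mimic_ct = c("709491003", "Suspected stroke mimic"),
    c("281900007", "No acute abnormality"))
  add(new_entry(sk$imaging, before_t0(admit + hours(stats::runif(1, 0.3, 0.8))),
                stats::setNames(list(
                  dv_coded("SNOMED-CT", img[1], img[2]),
                  dv_coded("SNOMED-CT", "12738006", "Brain")),
                  c(sk$p_img_findings, sk$p_img_site))))

  # medication order (baseline analgesic; warfarin when anticoagulated)
  med <- if (profile == "anticoagulated") c("B01AA03", "Warfarin")
    else c("N02BE01", "Paracetamol")
  add(new_entry(sk$medication, t0 - days(stats::runif(1, 5, 120)),
                stats::setNames(list(
                  dv_coded("ATC", med[1], med[2]),
                  dv_datetime(t0 - days(stats::runif(1, 121, 400)))),
                  c(sk$p_med, sk$p_med_start))))

  # baseline procedure (admission ECG)
  add(proc_entry("29303009", "Electrocardiogram",
                 before_t0(admit + hours(stats::runif(1, 0.1, 0.6)))))

  # profile-specific history
  hist_onset <- function(lo_d, hi_d) t0 - days(stats::runif(1, lo_d, hi_d))
  extra <- switch(profile,
    prior_ich = diag_entry("SNOMED-CT", "274100004", "Cerebral haemorrhage",
                           hist_onset(200, 1500), hist_onset(150, 199)),
    explosive_headache = diag_entry("SNOMED-CT", "21794005",
                                    "Thunderclap headache",
                                    onset + hours(stats::runif(1, 0, 0.5)),
                                    admit, confidence = "at0101"),
    postictal_paresis = if (stats::runif(1) < 0.5) {
      diag_entry("SNOMED-CT", "66264000", "Postictal paresis", onset, admit,
                 confidence = "at0101")
    } else {
      diag_entry("ICD10", "G83.8", "Postictal paresis", onset, admit,
                 confidence = "at0101")
    },
    septic_shock = diag_entry("SNOMED-CT", "76571007", "Septic shock",
                              onset - hours(stats::runif(1, 1, 24)), admit,
                              confidence = "at0101"),
    bleeding_disorder = diag_entry("SNOMED-CT", "64779008",
                                   "Blood coagulation disorder",
                                   hist_onset(300, 2000), hist_onset(200, 299)),
    serious_comorbidity = {
      pick <- sample(list(c("61420007", "Infectious endocarditis"),
                          c("3238004", "Pericarditis"),
                          c("84114007", "Severe heart failure"),
                          c("75694006", "Pancreatitis"),
                          c("235856003", "Severe liver damage")), 1)[[1]]
      diag_entry("SNOMED-CT", pick[1], pick[2], hist_onset(10, 400),
                 hist_onset(1, 9))
    },
    recent_lp = proc_entry("45036003", "Lumbar puncture",
                           t0 - hours(stats::runif(1, 30, 160))),
    lp_8days = proc_entry("45036003", "Lumbar puncture",
                          t0 - days(stats::runif(1, 8.1, 12))),
    organ_biopsy_2w = proc_entry("86273004", "Biopsy of parenchymatous organ",
                                 t0 - days(stats::runif(1, 8, 25))),
    duodenal_ulcer = diag_entry("ICD10", "K26", "Duodenal ulcer",
                                hist_onset(3, 25), hist_onset(1, 2.9)),
    prior_stroke_80d = diag_entry("SNOMED-CT", "230690007",
                                  "Cerebrovascular accident",
                                  hist_onset(30, 85), hist_onset(25, 29)),
    head_trauma_2m = diag_entry("SNOMED-CT", "82271004", "Head trauma",
                                hist_onset(10, 85), hist_onset(5, 9)),
    cns_operation_2m = proc_entry("25353009",
                                  "Operation in the central nervous system",
                                  t0 - days(stats::runif(1, 5, 85))),
    pregnancy = diag_entry("SNOMED-CT", "77386006", "Pregnancy",
                           hist_onset(30, 200), hist_onset(20, 29)),
    recent_childbirth = diag_entry("SNOMED-CT", "386216000", "Childbirth",
                                   hist_onset(5, 25), hist_onset(3, 4.9)),
    NULL)
  if (!is.null(extra)) add(extra)

  # intravenous fluids: saline for everyone, thrombolytic when given
  ivf_t <- before_t0(admit + hours(stats::runif(1, 0.1, 0.5)))
  add(new_entry(sk$ivf, ivf_t, stats::setNames(list(
    dv_coded("ATC", "B05BB01", "Electrolyte solution"), dv_datetime(ivf_t)),
    c(sk$p_fluid, sk$p_fluid_time))))
  if (lysis_given) {
    add(new_entry(sk$ivf, t0, stats::setNames(list(
      dv_coded("ATC", "B01AD02", "Alteplase"), dv_datetime(t0)),
      c(sk$p_fluid, sk$p_fluid_time))))
  }

  patient_case(case_id, t0, entries)
}

#' Generate a cohort of synthetic cases
#'
#' Cases cycle through the profile catalogue so that with the default size
#' every represented criterion is triggered by at least one case and left
#' untriggered by at least one. Each case draws from its own sub-seed
#' derived from `(master_seed, index)`, so any single case can be
#' regenerated independently.
#'
#' @param n Number of cases (default 49).
#' @param master_seed Integer master seed; the package default fixes the
#'   reference cohort.
#' @return List of [patient_case()] objects with ids `case_01` ...
#' @export
generate_cohort <- function(n = 49, master_seed = 20140301) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  profiles <- scenario_profiles()$profile_id
  lapply(seq_len(n), function(i) {
    profile <- profiles[(i - 1L) %% length(profiles) + 1L]
    sub_seed <- (as.numeric(master_seed) + 1000003 * i) %% .Machine$integer.max
    generate_case(profile, as.integer(sub_seed),
                  case_id = sprintf("case_%02d_%s", i, profile))
  })
}

#' Write a cohort to a directory
#'
#' @param cases List of cases.
#' @param dir Output directory (created if needed).
#' @param format `"dadl"` or `"json"`.
#' @return Invisibly, the written file paths.
#' @export
write_cohort <- function(cases, dir, format = c("dadl", "json")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(cases, function(case) {
    path <- file.path(dir, paste0(case$case_id,
                                  if (format == "dadl") ".case.dadl" else ".case.json"))
    if (format == "dadl") write_case(case, path) else write_case_json(case, path)
    path
  }, character(1))
  invisible(paths)
}

#' Read every case file in a directory
#'
#' @param dir Directory of `.case.dadl` / `.case.json` files.
#' @return List with `cases` (parsed cases) and `errors` (tibble of files
#'   that failed to parse and why).
#' @export
read_cohort <- function(dir) {
  files <- list.files(dir, pattern = "\\.case\\.(dadl|json)$", full.names = TRUE)
  cases <- list()
  errors <- list()
  for (f in files) {
    parsed <- tryCatch({
      if (grepl("\\.json$", f)) read_case_json(f) else read_case(f)
    }, error = function(e) e)
    if (inherits(parsed, "error")) {
      errors[[length(errors) + 1L]] <- tibble::tibble(
        file = f, error = conditionMessage(parsed))
    } else {
      cases[[length(cases) + 1L]] <- parsed
    }
  }
  list(cases = cases,
       errors = if (length(errors)) dplyr::bind_rows(errors) else
         tibble::tibble(file = character(), error = character()))
}
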