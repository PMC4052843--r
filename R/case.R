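#' Clinical entries and patient cases
#'
#' An entry is one archetype instance: a timestamped record (an observation,
#' evaluation, instruction or action) whose elements map archetype paths to
#' typed data values. A patient case is a set of entries plus a reference
#' time: the instant at which retrospective guideline evaluation is anchored
#' (for the shipped stroke content, the thrombolysis decision time).
#'
#' @name patient-case
NULL

#' Construct an entry
#'
#' @param archetype_id Archetype identifier; must be registered before
#'   validation or engine use.
#' @param event_time Timestamp of the clinical event (ISO 8601 string or
#'   POSIXct).
#' @param elements Named list mapping element paths to [datavalue]s.
#' @param entry_type Entry type; defaults to the registered schema's type at
#'   validation time, but may be stated explicitly.
#' @return An object of class `strokecds_entry`.
#' @export
new_entry <- function(archetype_id, event_time, elements = list(),
                      entry_type = NULL) {
  stopifnot(is.character(archetype_id), length(archetype_id) == 1L)
  if (length(elements)) {
    if (is.null(names(elements)) || any(!nzchar(names(elements)))) {
      stop("elements must be named by path", call. = FALSE)
    }
    if (anyDuplicated(names(elements))) {
      stop("duplicate element path within one entry", call. = FALSE)
    }
    ok <- vapply(elements, inherits, logical(1), "strokecds_dv")
    if (!all(ok)) stop("all element values must be data values", call. = FALSE)
  }
  t <- dv_datetime(event_time)$value
  if (!is.null(entry_type)) entry_type <- match.arg(entry_type, ENTRY_TYPES)
  structure(list(archetype_id = archetype_id, entry_type = entry_type,
                 event_time = t, elements = elements),
            class = "strokecds_entry")
}

#' Construct a patient case
#'
#' @param case_id Case identifier, unique within a cohort.
#' @param reference_time The retrospective evaluation instant (ISO 8601 string
#'   or POSIXct). Entries timestamped after it are allowed but provoke a
#'   warning, since look-back rules never see them.
#' @param entries List of [new_entry()] objects.
#' @return An object of class `strokecds_case`.
#' @export
patient_case <- function(case_id, reference_time, entries = list()) {
  stopifnot(is.character(case_id), length(case_id) == 1L, nzchar(case_id))
  ref <- dv_datetime(reference_time)$value
  ok <- vapply(entries, inherits, logical(1), "strokecds_entry")
  if (length(entries) && !all(ok)) {
    stop("entries must be strokecds_entry objects", call. = FALSE)
  }
  late <- vapply(entries, function(e) as.numeric(e$event_time) > as.numeric(ref),
                 logical(1))
  if (any(late)) {
    warning("case ", case_id, ": ", sum(late),
            " entr(ies) timestamped after the reference time", call. = FALSE)
  }
  structure(list(case_id = case_id, reference_time = ref, entries = entries),
            class = "strokecds_case")
}

#' @export
print.strokecds_case <- function(x, ...) {
  cat("<patient case> ", x$case_id, ": ", length(x$entries),
      " entries, reference ", format_iso_datetime(x$reference_time), "\n", sep = "")
  invisible(x)
}

#' Validate an entry against the schema registry
#'
#' @param entry A [new_entry()].
#' @param registry A [schema_registry()] in which the entry's archetype is
#'   registered (unknown archetype is an error, not a violation).
#' @return A tibble of violations with columns `path`, `problem`, `detail`;
#'   zero rows means the entry is valid.
#' @export
validate_entry <- function(entry, registry) {
  stopifnot(inherits(entry, "strokecds_entry"))
  schema <- get_schema(registry, entry$archetype_id)
  v <- list()
  note <- function(path, problem, detail) {
    v[[length(v) + 1L]] <<- tibble::tibble(path = path, problem = problem,
                                           detail = detail)
  }
  if (!is.null(entry$entry_type) && entry$entry_type != schema$entry_type) {
    note(NA_character_, "entry_type",
         paste0("entry says ", entry$entry_type, ", schema says ", schema$entry_type))
  }
  for (path in names(entry$elements)) {
    def <- schema$elements[[path]]
    val <- entry$elements[[path]]
    if (is.null(def)) {
      note(path, "unknown_path", "path not declared in schema")
      next
    }
    if (val$kind != def$kind) {
      note(path, "kind", paste0("expected ", def$kind, ", got ", val$kind))
      next
    }
    if (def$kind == "quantity" && val$unit != def$unit) {
      note(path, "unit", paste0("expected ", def$unit, ", got ", val$unit))
    }
    if (def$kind == "coded_text" && !is.null(def$codes) &&
        val$system == "local" && !(val$code %in% names(def$codes))) {
      note(path, "code", paste0("local code ", val$code, " not allowed here"))
    }
  }
  if (length(v)) dplyr::bind_rows(v) else {
    tibble::tibble(path = character(), problem = character(), detail = character())
  }
}

#' Validate every entry of a case
#'
#' @param case A [patient_case()].
#' @inheritParams validate_entry
#' @return Tibble of violations with an extra leading `entry` index column.
#' @export
validate_case <- function(case, registry) {
  stopifnot(inherits(case, "strokecds_case"))
  out <- purrr::imap(case$entries, function(e, i) {
    dplyr::mutate(validate_entry(e, registry), entry = i, .before = 1)
  })
  dplyr::bind_rows(out)
}

#' Read all values at one archetype path across a case
#'
#' Returns the values stored at `path` in every entry of the given archetype,
#' in ascending event-time order. Missing archetypes or paths simply yield an
#' empty list: absence of data is an ordinary state, not an error.
#'
#' @param case A [patient_case()].
#' @param archetype_id Archetype identifier.
#' @param path Element path within that archetype.
#' @return List of [datavalue]s (possibly empty).
#' @export
get_value <- function(case, archetype_id, path) {
  stopifnot(inherits(case, "strokecds_case"))
  hits <- Filter(function(e) e$archetype_id == archetype_id &&
                   !is.null(e$elements[[path]]), case$entries)
  if (!length(hits)) return(list())
  ord <- order(vapply(hits, function(e) as.numeric(e$event_time), numeric(1)))
  lapply(hits[ord], function(e) e$elements[[path]])
}

# Entries of one archetype, ascending event time.
entries_of <- function(case, archetype_id) {
  hits <- Filter(function(e) e$archetype_id == archetype_id, case$entries)
  if (!length(hits)) return(list())
  hits[order(vapply(hits, function(e) as.numeric(e$event_time), numeric(1)))]
}

# Structural equality of two cases (field-for-field, second-resolution times).
case_equal <- function(a, b) {
  if (a$case_id != b$case_id) return(FALSE)
  if (as.numeric(a$reference_time) != as.numeric(b$reference_time)) return(FALSE)
  if (length(a$entries) != length(b$entries)) return(FALSE)
  for (i in seq_along(a$entries)) {
    ea <- a$entries[[i]]; eb <- b$entries[[i]]
    if (ea$archetype_id != eb$archetype_id) return(FALSE)
    if (!identical(ea$entry_type, eb$entry_type)) return(FALSE)
    if (as.numeric(ea$event_time) != as.numeric(eb$event_time)) return(FALSE)
    if (!setequal(names(ea$elements), names(eb$elements))) return(FALSE)
    for (p in names(ea$elements)) {
      if (!dv_equal(ea$elements[[p]], eb$elements[[p]])) return(FALSE)
      if (ea$elements[[p]]$kind == "coded_text" &&
          ea$elements[[p]]$display != eb$elements[[p]]$display) return(FALSE)
    }
  }
  TRUE
}
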