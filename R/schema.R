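#' Archetype schemas and the schema registry
#'
#' An archetype schema is the data contract for one clinical concept: it names
#' the archetype, fixes its entry type (OBSERVATION, EVALUATION, INSTRUCTION or
#' ACTION), and declares each element path together with the kind of value it
#' holds, a fixed unit where the kind is a quantity, and the allowed local
#' codes where the kind is coded text. Both patient-case entries and guideline
#' bindings are validated against the registry of schemas.
#'
#' Units are fixed per element: a value in a different unit is a validation
#' error, never converted.
#'
#' @name archetype-schema
NULL

ENTRY_TYPES <- c("OBSERVATION", "EVALUATION", "INSTRUCTION", "ACTION")
DV_KINDS <- c("count", "quantity", "boolean", "text", "coded_text",
              "date_time", "duration")

PATH_REGEX <- "^(/[A-Za-z_][A-Za-z0-9_]*(\\[at[0-9]+(\\.[0-9]+)*\\])?)+$"

is_valid_path <- function(path) {
  is.character(path) && length(path) == 1L && grepl(PATH_REGEX, path)
}

#' Declare one element of an archetype schema
#'
#' @param kind Value kind, one of `"count"`, `"quantity"`, `"boolean"`,
#'   `"text"`, `"coded_text"`, `"date_time"`, `"duration"`.
#' @param unit Required unit string when `kind == "quantity"`, e.g. `"mmol/l"`.
#' @param codes Optional named character vector of allowed local codes
#'   (names are at-codes, values their displays) when `kind == "coded_text"`.
#'   `NULL` leaves the code set open (external terminology codes).
#' @return An element definition used by [archetype_schema()].
#' @export
element_def <- function(kind, unit = NULL, codes = NULL) {
  kind <- match.arg(kind, DV_KINDS)
  if (kind == "quantity") {
    if (is.null(unit) || !nzchar(unit)) {
      stop("quantity elements need a fixed unit", call. = FALSE)
    }
  } else if (!is.null(unit)) {
    stop("only quantity elements carry a unit", call. = FALSE)
  }
  if (!is.null(codes)) {
    if (kind != "coded_text") stop("only coded_text elements carry codes", call. = FALSE)
    if (is.null(names(codes)) || anyDuplicated(names(codes))) {
      stop("codes must be uniquely named (at-code -> display)", call. = FALSE)
    }
  }
  structure(list(kind = kind, unit = unit, codes = codes),
            class = "strokecds_element_def")
}

#' @rdname archetype-schema
#' @param archetype_id Archetype identifier, e.g.
#'   `"openEHR-EHR-OBSERVATION.lab_test-blood_glucose"`.
#' @param entry_type One of `"OBSERVATION"`, `"EVALUATION"`, `"INSTRUCTION"`,
#'   `"ACTION"`.
#' @param elements Named list of [element_def()]s keyed by element path.
#' @return An object of class `strokecds_schema`.
#' @export
archetype_schema <- function(archetype_id, entry_type, elements = list()) {
  stopifnot(is.character(archetype_id), length(archetype_id) == 1L,
            nzchar(archetype_id))
  entry_type <- match.arg(entry_type, ENTRY_TYPES)
  if (length(elements)) {
    if (is.null(names(elements)) || any(!nzchar(names(elements)))) {
      stop("elements must be named by path", call. = FALSE)
    }
    if (anyDuplicated(names(elements))) {
      stop("duplicate element paths in schema ", archetype_id, call. = FALSE)
    }
    bad <- names(elements)[!vapply(names(elements), is_valid_path, logical(1))]
    if (length(bad)) {
      stop("malformed element path(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    ok <- vapply(elements, inherits, logical(1), "strokecds_element_def")
    if (!all(ok)) stop("all elements must be element_def()s", call. = FALSE)
    at_codes <- unlist(lapply(elements, function(e) names(e$codes)), use.names = FALSE)
    at_codes <- at_codes[grepl("^at[0-9]", at_codes)]
    if (anyDuplicated(at_codes)) {
      stop("duplicate local at-codes within schema ", archetype_id, call. = FALSE)
    }
  }
  structure(list(archetype_id = archetype_id, entry_type = entry_type,
                 elements = elements),
            class = "strokecds_schema")
}

#' @export
print.strokecds_schema <- function(x, ...) {
  cat("<archetype schema> ", x$archetype_id, " (", x$entry_type, ", ",
      length(x$elements), " elements)\n", sep = "")
  invisible(x)
}

#' Create an empty schema registry
#'
#' The registry is a mutable handle (environment-backed): [register_schema()]
#' adds to it in place, so one registry can be shared across guidelines,
#' cases and the engine.
#'
#' @return An object of class `strokecds_registry`.
#' @export
schema_registry <- function() {
  structure(list(env = new.env(parent = emptyenv())),
            class = "strokecds_registry")
}

#' Register an archetype schema
#'
#' @param registry A [schema_registry()].
#' @param schema An [archetype_schema()]. Registering the same archetype id
#'   twice is an error.
#' @return The registry, invisibly.
#' @export
register_schema <- function(registry, schema) {
  stopifnot(inherits(registry, "strokecds_registry"),
            inherits(schema, "strokecds_schema"))
  if (!is.null(registry$env[[schema$archetype_id]])) {
    stop("archetype already registered: ", schema$archetype_id, call. = FALSE)
  }
  assign(schema$archetype_id, schema, envir = registry$env)
  invisible(registry)
}

#' Look up a schema by archetype id
#'
#' @inheritParams register_schema
#' @param archetype_id Archetype identifier.
#' @return The schema; error if unknown.
#' @export
get_schema <- function(registry, archetype_id) {
  s <- registry$env[[archetype_id]]
  if (is.null(s)) stop("unknown archetype: ", archetype_id, call. = FALSE)
  s
}

#' @rdname get_schema
#' @return `schema_ids()`: sorted character vector of registered ids.
#' @export
schema_ids <- function(registry) {
  sort(ls(registry$env))
}

#' @export
print.strokecds_registry <- function(x, ...) {
  cat("<schema registry> ", length(ls(x$env)), " archetypes\n", sep = "")
  invisible(x)
}
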