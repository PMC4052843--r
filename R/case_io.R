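#' Read and write patient cases
#'
#' Cases are stored one per file in either of two equivalent forms:
#'
#' * a dADL-style text dialect (`.case.dadl`, see [odin]) in which each
#'   element value is a type-tagged block, e.g.
#'   `(DV_QUANTITY) <magnitude = <2.9> units = <"mmol/l">>`;
#' * a canonical JSON serialization (`.case.json`), the normative structured
#'   form.
#'
#' Reading the written form of a case reproduces it field for field, in both
#' formats.
#'
#' @param case A [patient_case()].
#' @param path File path; for the readers, a path to an existing file.
#' @param text Alternatively, the document as a single string.
#' @return The writers return `path` (or the serialized string when `path` is
#'   `NULL`), invisibly when writing to a file; readers return a
#'   [patient_case()].
#' @name case-io
NULL

RM_TYPE_OF_KIND <- c(count = "DV_COUNT", quantity = "DV_QUANTITY",
                     boolean = "DV_BOOLEAN", text = "DV_TEXT",
                     coded_text = "DV_CODED_TEXT", date_time = "DV_DATE_TIME",
                     duration = "DV_DURATION")

dv_to_odin <- function(dv) {
  tag <- unname(RM_TYPE_OF_KIND[dv$kind])
  sc <- function(type, value) list(kind = "scalar", tag = NULL,
                                   scalar_type = type, value = value)
  attrs <- switch(dv$kind,
    count = list(magnitude = sc("number", dv$value)),
    quantity = list(magnitude = sc("number", dv$magnitude),
                    units = sc("string", dv$unit)),
    boolean = list(value = sc("bool", dv$value)),
    text = list(value = sc("string", dv$value)),
    coded_text = list(terminology = sc("string", dv$system),
                      code = sc("string", dv$code),
                      value = sc("string", dv$display)),
    date_time = list(value = sc("datetime", dv$value)),
    duration = list(value = sc("duration", dv$value)))
  list(kind = "block", tag = tag, attrs = attrs)
}

odin_to_dv <- function(node) {
  if (node$kind != "block" || is.null(node$tag)) {
    stop("element value must be a type-tagged block", call. = FALSE)
  }
  switch(node$tag,
    DV_COUNT = dv_count(odin_scalar_value(node, "magnitude")),
    DV_QUANTITY = dv_quantity(odin_scalar_value(node, "magnitude"),
                              odin_scalar_value(node, "units")),
    DV_BOOLEAN = dv_boolean(odin_scalar_value(node, "value")),
    DV_TEXT = dv_text(odin_scalar_value(node, "value")),
    DV_CODED_TEXT = dv_coded(odin_scalar_value(node, "terminology"),
                             odin_scalar_value(node, "code"),
                             odin_scalar_value(node, "value")),
    DV_DATE_TIME = dv_datetime(odin_scalar_value(node, "value")),
    DV_DURATION = dv_duration(odin_scalar_value(node, "value")),
    stop("unknown data value type tag: ", node$tag, call. = FALSE))
}

case_to_odin <- function(case) {
  sc <- function(type, value) list(kind = "scalar", tag = NULL,
                                   scalar_type = type, value = value)
  entry_nodes <- list()
  for (i in seq_along(case$entries)) {
    e <- case$entries[[i]]
    el_nodes <- lapply(e$elements, dv_to_odin)
    attrs <- list(archetype_id = sc("string", e$archetype_id))
    if (!is.null(e$entry_type)) attrs$entry_type <- sc("string", e$entry_type)
    attrs$event_time <- sc("datetime", e$event_time)
    attrs$elements <- list(kind = "block", tag = NULL, attrs = el_nodes)
    entry_nodes[[as.character(i)]] <- list(kind = "block", tag = NULL, attrs = attrs)
  }
  list(kind = "block", tag = NULL, attrs = list(
    case_id = sc("string", case$case_id),
    reference_time = sc("datetime", case$reference_time),
    entries = list(kind = "block", tag = NULL, attrs = entry_nodes)))
}

odin_to_case <- function(tree) {
  entries_node <- odin_attr(tree, "entries", required = FALSE)
  entries <- list()
  if (!is.null(entries_node)) {
    for (key in names(entries_node$attrs)) {
      en <- entries_node$attrs[[key]]
      elements <- list()
      el_node <- odin_attr(en, "elements", required = FALSE)
      if (!is.null(el_node)) elements <- lapply(el_node$attrs, odin_to_dv)
      entries[[length(entries) + 1L]] <- new_entry(
        archetype_id = odin_scalar_value(en, "archetype_id"),
        event_time = odin_scalar_value(en, "event_time"),
        elements = elements,
        entry_type = odin_scalar_value(en, "entry_type", required = FALSE))
    }
  }
  patient_case(case_id = odin_scalar_value(tree, "case_id"),
               reference_time = odin_scalar_value(tree, "reference_time"),
               entries = entries)
}

#' @rdname case-io
#' @export
write_case <- function(case, path = NULL) {
  stopifnot(inherits(case, "strokecds_case"))
  txt <- paste0(odin_serialize(case_to_odin(case)), "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(path)
}

#' @rdname case-io
#' @export
read_case <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  }
  odin_to_case(odin_parse(text))
}

case_to_list <- function(case) {
  list(
    case_id = case$case_id,
    reference_time = format_iso_datetime(case$reference_time),
    entries = lapply(case$entries, function(e) {
      el <- lapply(e$elements, function(dv) {
        base <- list(type = unname(RM_TYPE_OF_KIND[dv$kind]))
        c(base, switch(dv$kind,
          count = list(magnitude = dv$value),
          quantity = list(magnitude = dv$magnitude, units = dv$unit),
          boolean = list(value = dv$value),
          text = list(value = dv$value),
          coded_text = list(terminology = dv$system, code = dv$code,
                            value = dv$display),
          date_time = list(value = format_iso_datetime(dv$value)),
          duration = list(value = dv$value)))
      })
      out <- list(archetype_id = e$archetype_id)
      if (!is.null(e$entry_type)) out$entry_type <- e$entry_type
      out$event_time <- format_iso_datetime(e$event_time)
      out$elements <- el
      out
    }))
}

list_to_case <- function(x) {
  entries <- lapply(x$entries, function(e) {
    elements <- lapply(e$elements, function(v) {
      switch(v$type,
        DV_COUNT = dv_count(v$magnitude),
        DV_QUANTITY = dv_quantity(v$magnitude, v$units),
        DV_BOOLEAN = dv_boolean(v$value),
        DV_TEXT = dv_text(v$value),
        DV_CODED_TEXT = dv_coded(v$terminology, v$code, v$value),
        DV_DATE_TIME = dv_datetime(v$value),
        DV_DURATION = dv_duration(v$value),
        stop("unknown data value type: ", v$type, call. = FALSE))
    })
    new_entry(e$archetype_id, e$event_time, elements,
              entry_type = e$entry_type)
  })
  patient_case(x$case_id, x$reference_time, entries)
}

#' @rdname case-io
#' @export
write_case_json <- function(case, path = NULL) {
  stopifnot(inherits(case, "strokecds_case"))
  js <- jsonlite::toJSON(case_to_list(case), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname case-io
#' @export
read_case_json <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  list_to_case(jsonlite::fromJSON(text, simplifyVector = FALSE))
}
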