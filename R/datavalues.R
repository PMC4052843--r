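#' Typed clinical data values
#'
#' Constructors for the small set of typed values a clinical entry may carry,
#' modelled after the openEHR reference-model data types: counts, physical
#' quantities with units, booleans, plain text, terminology-coded text,
#' timestamps and signed durations. Every element of a patient case holds
#' exactly one of these.
#'
#' Timestamps are stored at second resolution in UTC; inputs may carry any
#' explicit UTC offset, which is normalised away. Durations are ISO 8601
#' period strings restricted to day/hour/minute/second components (calendar
#' months are ambiguous and rejected).
#'
#' @param value The payload: an integer for `dv_count()`, logical for
#'   `dv_boolean()`, character for `dv_text()`, an ISO 8601 string or POSIXct
#'   for `dv_datetime()`, an ISO 8601 period string for `dv_duration()`.
#' @param magnitude,unit Numeric magnitude and non-empty unit string for
#'   `dv_quantity()`.
#' @param system,code,display Code system id, code and optional human-readable
#'   display for `dv_coded()`.
#' @return A data value: a list with class `strokecds_dv` and a kind-specific
#'   subclass; inspect with [dv_kind()].
#' @examples
#' dv_quantity(2.9, "mmol/l")
#' dv_coded("SNOMED-CT", "50960005", "Haemorrhage")
#' dv_datetime("2014-03-01T10:30:00Z")
#' @name datavalue
NULL

new_dv <- function(kind, fields) {
  structure(c(list(kind = kind), fields),
            class = c(paste0("dv_", kind), "strokecds_dv"))
}

#' @rdname datavalue
#' @export
dv_count <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value != as.integer(value)) {
    stop("dv_count() requires a single integer value", call. = FALSE)
  }
  new_dv("count", list(value = as.integer(value)))
}

#' @rdname datavalue
#' @export
dv_quantity <- function(magnitude, unit) {
  if (!is.numeric(magnitude) || length(magnitude) != 1L || is.na(magnitude)) {
    stop("dv_quantity() requires a single numeric magnitude", call. = FALSE)
  }
  if (!is.character(unit) || length(unit) != 1L || !nzchar(unit)) {
    stop("dv_quantity() requires a non-empty unit", call. = FALSE)
  }
  new_dv("quantity", list(magnitude = as.numeric(magnitude), unit = unit))
}

#' @rdname datavalue
#' @export
dv_boolean <- function(value) {
  if (!is.logical(value) || length(value) != 1L || is.na(value)) {
    stop("dv_boolean() requires TRUE or FALSE", call. = FALSE)
  }
  new_dv("boolean", list(value = value))
}

#' @rdname datavalue
#' @export
dv_text <- function(value) {
  if (!is.character(value) || length(value) != 1L || is.na(value)) {
    stop("dv_text() requires a single string", call. = FALSE)
  }
  new_dv("text", list(value = value))
}

#' @rdname datavalue
#' @export
dv_coded <- function(system, code, display = "") {
  stopifnot(is.character(system), length(system) == 1L, nzchar(system),
            is.character(code), length(code) == 1L, nzchar(code),
            is.character(display), length(display) == 1L)
  new_dv("coded_text", list(system = system, code = code, display = display))
}

#' @rdname datavalue
#' @export
dv_datetime <- function(value) {
  t <- if (inherits(value, "POSIXct")) {
    as.POSIXct(round(as.numeric(value)), origin = "1970-01-01", tz = "UTC")
  } else {
    parse_iso_datetime(value)
  }
  new_dv("date_time", list(value = t))
}

#' @rdname datavalue
#' @export
dv_duration <- function(value) {
  secs <- parse_iso_duration(value)
  new_dv("duration", list(value = value, seconds = secs))
}

#' Kind of a data value
#'
#' @param x A data value created by one of the [datavalue] constructors.
#' @return One of `"count"`, `"quantity"`, `"boolean"`, `"text"`,
#'   `"coded_text"`, `"date_time"`, `"duration"`.
#' @export
dv_kind <- function(x) {
  stopifnot(inherits(x, "strokecds_dv"))
  x$kind
}

#' @export
print.strokecds_dv <- function(x, ...) {
  cat("<", x$kind, "> ", format_dv(x), "\n", sep = "")
  invisible(x)
}

format_dv <- function(x) {
  switch(x$kind,
    count = as.character(x$value),
    quantity = paste0(format(x$magnitude), " ", x$unit),
    boolean = if (x$value) "true" else "false",
    text = x$value,
    coded_text = paste0(x$system, "::", x$code,
                        if (nzchar(x$display)) paste0("|", x$display, "|") else ""),
    date_time = format_iso_datetime(x$value),
    duration = x$value)
}

#' Structural equality of two data values
#'
#' Equality is by kind and payload; coded text compares system and code but
#' not the display string, and datetimes compare at second resolution.
#'
#' @param a,b Data values.
#' @return `TRUE` or `FALSE`.
#' @export
dv_equal <- function(a, b) {
  if (a$kind != b$kind) return(FALSE)
  switch(a$kind,
    count = a$value == b$value,
    quantity = a$magnitude == b$magnitude && a$unit == b$unit,
    boolean = a$value == b$value,
    text = a$value == b$value,
    coded_text = a$system == b$system && a$code == b$code,
    date_time = as.numeric(a$value) == as.numeric(b$value),
    duration = a$seconds == b$seconds)
}

# Ordering comparison for the ordered kinds; NA_integer_ when the pair is not
# comparable (mixed kinds other than count/quantity magnitudes, units differ).
dv_compare <- function(a, b) {
  num <- function(x) switch(x$kind, count = x$value, quantity = x$magnitude, NULL)
  if (!is.null(num(a)) && !is.null(num(b))) {
    if (a$kind == "quantity" && b$kind == "quantity" && a$unit != b$unit) {
      return(NA_integer_)
    }
    return(as.integer(sign(num(a) - num(b))))
  }
  if (a$kind == "date_time" && b$kind == "date_time") {
    return(as.integer(sign(as.numeric(a$value) - as.numeric(b$value))))
  }
  if (a$kind == "duration" && b$kind == "duration") {
    return(as.integer(sign(a$seconds - b$seconds)))
  }
  NA_integer_
}

#' Parse and format ISO 8601 timestamps (UTC, second resolution)
#'
#' @param x An ISO 8601 string such as `"2014-03-01T10:30:00Z"` or
#'   `"2014-03-01T10:30:00+02:00"`; an explicit zone designator is required.
#' @return `parse_iso_datetime()` a UTC POSIXct; `format_iso_datetime()` the
#'   canonical `...Z` string.
#' @export
parse_iso_datetime <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- regmatches(x, regexec(
    "^(\\d{4})-(\\d{2})-(\\d{2})T(\\d{2}):(\\d{2}):(\\d{2})(Z|[+-]\\d{2}:\\d{2})$",
    x))[[1]]
  if (length(m) == 0L) {
    stop("not an ISO 8601 datetime with explicit timezone: ", x, call. = FALSE)
  }
  base <- as.POSIXct(sprintf("%s-%s-%s %s:%s:%s", m[2], m[3], m[4], m[5], m[6], m[7]),
                     tz = "UTC")
  if (is.na(base)) stop("invalid calendar datetime: ", x, call. = FALSE)
  if (m[8] != "Z") {
    sgn <- if (substr(m[8], 1, 1) == "-") -1 else 1
    off <- sgn * (as.integer(substr(m[8], 2, 3)) * 3600 +
                    as.integer(substr(m[8], 5, 6)) * 60)
    base <- base - off
  }
  base
}

#' @rdname parse_iso_datetime
#' @param t A POSIXct.
#' @export
format_iso_datetime <- function(t) {
  format(as.POSIXct(t, tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Parse an ISO 8601 duration into seconds
#'
#' Supports signed periods built from weeks, days, hours, minutes and seconds
#' (e.g. `"PT4H30M"`, `"P90D"`, `"-PT30M"`). Year and month components are
#' rejected: their length depends on the calendar anchor and every interval
#' used by the shipped guideline content is a fixed span.
#'
#' @param x An ISO 8601 period string.
#' @return Signed number of seconds.
#' @export
parse_iso_duration <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- regmatches(x, regexec(
    "^(-)?P(?:(\\d+)W)?(?:(\\d+)D)?(?:T(?:(\\d+)H)?(?:(\\d+)M)?(?:(\\d+(?:\\.\\d+)?)S)?)?$",
    x))[[1]]
  if (length(m) == 0L || x %in% c("P", "-P", "PT", "-PT")) {
    stop("not a supported ISO 8601 duration: ", x, call. = FALSE)
  }
  n <- function(i) if (nzchar(m[i])) as.numeric(m[i]) else 0
  secs <- n(3) * 604800 + n(4) * 86400 + n(5) * 3600 + n(6) * 60 + n(7)
  if (m[2] == "-") -secs else secs
}
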