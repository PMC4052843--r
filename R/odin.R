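#' A minimal key = <value> tree dialect
#'
#' Patient cases and guideline files are stored in a small text notation in
#' the style of openEHR's dADL/ODIN: nested attribute blocks
#' `key = <...>`, keys either bare identifiers or bracketed strings
#' (`["/data[at0001]"] = <...>`), optional type tags before a block
#' (`(DV_QUANTITY) <...>`), scalar leaves (strings, numbers, booleans,
#' ISO 8601 datetimes and durations) and comma-separated scalar lists.
#' `--` starts a comment running to end of line.
#'
#' `odin_parse()` returns a nested node structure; malformed input raises an
#' error naming the line and column. `odin_serialize()` renders a node back
#' to text; parse and serialize are mutually inverse on well-formed trees.
#'
#' @param text A single string (the whole document).
#' @return For `odin_parse()`, a node: a list with `kind` (`"block"`,
#'   `"scalar"` or `"list"`), `tag` (type tag or `NULL`), and `attrs` /
#'   `value` / `values` accordingly.
#' @keywords internal
#' @name odin
NULL

ODIN_TOKEN_REGEX <- paste0(
  "(--[^\n]*)",                                                        # comment
  "|(\"(?:[^\"\\\\]|\\\\.)*\")",                                       # string
  "|(\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}(?:Z|[+-]\\d{2}:\\d{2}))", # datetime
  "|(-?\\d+(?:\\.\\d+)?)",                                             # number
  "|([A-Za-z_][A-Za-z0-9_]*)",                                         # ident
  "|([<>=,()\\[\\]])"                                                  # punct
)

odin_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- gregexpr(ODIN_TOKEN_REGEX, text, perl = TRUE)[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  if (starts[1] == -1L) { starts <- integer(); lens <- integer() }
  # every character outside a token must be whitespace
  covered <- rep(FALSE, nchar(text))
  for (i in seq_along(starts)) covered[seq(starts[i], length.out = lens[i])] <- TRUE
  chars <- strsplit(text, "")[[1]]
  stray <- which(!covered & !grepl("^\\s$", chars))
  line_of <- function(pos) {
    prefix <- substr(text, 1L, pos - 1L)
    nl <- gregexpr("\n", prefix, fixed = TRUE)[[1]]
    n <- if (nl[1] == -1L) 0L else length(nl)
    col <- pos - (if (n == 0L) 0L else max(nl))
    c(line = n + 1L, col = col)
  }
  if (length(stray)) {
    lc <- line_of(stray[1])
    stop(sprintf("parse error at line %d, column %d: unexpected character '%s'",
                 lc[1], lc[2], chars[stray[1]]), call. = FALSE)
  }
  toks <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    s <- substr(text, starts[i], starts[i] + lens[i] - 1L)
    lc <- line_of(starts[i])
    type <- if (startsWith(s, "--")) "comment"
      else if (startsWith(s, "\"")) "string"
      else if (grepl("^\\d{4}-\\d{2}-\\d{2}T", s)) "datetime"
      else if (grepl("^-?\\d", s)) "number"
      else if (s %in% c("true", "false")) "bool"
      else if (grepl("^[A-Za-z_]", s)) {
        if (grepl("^P", s) && !inherits(try(parse_iso_duration(s), silent = TRUE),
                                        "try-error")) "duration" else "ident"
      } else "punct"
    toks[[i]] <- list(type = type, text = s, line = lc[1], col = lc[2])
  }
  Filter(function(t) t$type != "comment", toks)
}

unquote_odin_string <- function(s) {
  body <- substr(s, 2L, nchar(s) - 1L)
  body <- gsub("\\\\n", "\n", body)
  body <- gsub("\\\\\"", "\"", body)
  gsub("\\\\\\\\", "\\\\", body)
}

quote_odin_string <- function(s) {
  s <- gsub("\\\\", "\\\\\\\\", s)
  s <- gsub("\"", "\\\\\"", s)
  s <- gsub("\n", "\\\\n", s)
  paste0("\"", s, "\"")
}

odin_scalar <- function(type, text) {
  value <- switch(type,
    string = unquote_odin_string(text),
    number = as.numeric(text),
    bool = identical(text, "true"),
    datetime = parse_iso_datetime(text),
    duration = text)
  list(kind = "scalar", tag = NULL, scalar_type = type, value = value)
}

# Recursive-descent parser over the token list. `pos` is a mutable index
# carried in an environment so helpers can advance it.
odin_parse <- function(text) {
  toks <- odin_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$pos <- 1L
  peek <- function(ahead = 0L) {
    i <- st$pos + ahead
    if (i > length(toks)) {
      last <- if (length(toks)) toks[[length(toks)]] else list(line = 1L, col = 1L)
      list(type = "eof", text = "<end of input>", line = last$line,
           col = last$col)
    } else {
      toks[[i]]
    }
  }
  advance <- function() { t <- peek(); st$pos <- st$pos + 1L; t }
  fail <- function(t, msg) {
    where <- if (is.na(t$line)) "at end of input"
      else sprintf("at line %d, column %d", t$line, t$col)
    stop(sprintf("parse error %s: %s (saw '%s')", where, msg, t$text),
         call. = FALSE)
  }
  expect <- function(text) {
    t <- advance()
    if (t$text != text) fail(t, paste0("expected '", text, "'"))
    t
  }

  parse_key <- function() {
    t <- advance()
    if (t$type == "ident") return(t$text)
    if (t$text == "[") {
      s <- advance()
      if (s$type != "string") fail(s, "expected quoted key inside [ ]")
      expect("]")
      return(unquote_odin_string(s$text))
    }
    fail(t, "expected attribute key")
  }

  parse_attrs <- function(stop_at_gt) {
    attrs <- list()
    repeat {
      t <- peek()
      if (t$type == "eof") {
        if (stop_at_gt) fail(t, "unterminated block: missing '>'")
        break
      }
      if (t$text == ">" && stop_at_gt) break
      key <- parse_key()
      expect("=")
      node <- parse_value()
      if (!is.null(attrs[[key]])) {
        fail(t, paste0("duplicate key '", key, "'"))
      }
      attrs[[key]] <- node
    }
    attrs
  }

  parse_value <- function() {
    tag <- NULL
    t <- peek()
    if (t$text == "(") {
      advance()
      tg <- advance()
      if (tg$type != "ident") fail(tg, "expected type tag")
      tag <- tg$text
      expect(")")
    }
    expect("<")
    t <- peek()
    scalar_types <- c("string", "number", "bool", "datetime", "duration")
    if (t$text == ">" && is.null(tag)) {  # empty block
      advance()
      return(list(kind = "block", tag = NULL, attrs = list()))
    }
    if (t$type %in% scalar_types) {
      values <- list(odin_scalar(t$type, t$text))
      advance()
      while (peek()$text == ",") {
        advance()
        nx <- advance()
        if (!(nx$type %in% scalar_types)) fail(nx, "expected scalar after ','")
        values[[length(values) + 1L]] <- odin_scalar(nx$type, nx$text)
      }
      expect(">")
      if (length(values) == 1L) {
        out <- values[[1]]
        out$tag <- tag
        return(out)
      }
      return(list(kind = "list", tag = tag, values = values))
    }
    attrs <- parse_attrs(stop_at_gt = TRUE)
    expect(">")
    list(kind = "block", tag = tag, attrs = attrs)
  }

  attrs <- parse_attrs(stop_at_gt = FALSE)
  if (st$pos <= length(toks)) fail(peek(), "trailing content")
  list(kind = "block", tag = NULL, attrs = attrs)
}

format_odin_scalar <- function(node) {
  switch(node$scalar_type,
    string = quote_odin_string(node$value),
    number = {
      v <- node$value
      if (!is.finite(v)) stop("cannot serialize non-finite number", call. = FALSE)
      format(v, scientific = FALSE, trim = TRUE, digits = 15)
    },
    bool = if (node$value) "true" else "false",
    datetime = format_iso_datetime(node$value),
    duration = node$value)
}

odin_serialize <- function(node, indent = 0L) {
  stopifnot(identical(node$kind, "block"))
  pad <- strrep("    ", indent)
  out <- character()
  for (key in names(node$attrs)) {
    child <- node$attrs[[key]]
    keytxt <- if (grepl("^[A-Za-z_][A-Za-z0-9_]*$", key)) key
      else paste0("[", quote_odin_string(key), "]")
    tagtxt <- if (!is.null(child$tag)) paste0("(", child$tag, ") ") else ""
    if (child$kind == "scalar") {
      out <- c(out, paste0(pad, keytxt, " = ", tagtxt, "<",
                           format_odin_scalar(child), ">"))
    } else if (child$kind == "list") {
      inner <- vapply(child$values, format_odin_scalar, character(1))
      out <- c(out, paste0(pad, keytxt, " = ", tagtxt, "<",
                           paste(inner, collapse = ", "), ">"))
    } else {
      out <- c(out, paste0(pad, keytxt, " = ", tagtxt, "<"),
               odin_serialize(child, indent + 1L),
               paste0(pad, ">"))
    }
  }
  paste(out, collapse = "\n")
}

# Convenience accessors with informative errors.
odin_attr <- function(node, key, required = TRUE) {
  v <- node$attrs[[key]]
  if (is.null(v) && required) stop("missing key '", key, "'", call. = FALSE)
  v
}

odin_scalar_value <- function(node, key, required = TRUE) {
  v <- odin_attr(node, key, required)
  if (is.null(v)) return(NULL)
  if (v$kind != "scalar") stop("key '", key, "' is not a scalar", call. = FALSE)
  v$value
}

# A scalar list key may be written with one element; normalise to a list.
odin_list_values <- function(node, key, required = TRUE) {
  v <- odin_attr(node, key, required)
  if (is.null(v)) return(list())
  if (v$kind == "scalar") return(list(v$value))
  if (v$kind == "list") return(lapply(v$values, `[[`, "value"))
  stop("key '", key, "' is not a scalar list", call. = FALSE)
}
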