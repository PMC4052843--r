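#' The rule expression dialect
#'
#' Guideline conditions and actions are written in a compact expression
#' dialect. Variables are guideline-local codes (`$gt0008`) bound to
#' archetype elements; `currentDateTime` names the evaluation instant.
#' Conditions combine comparisons (`==`, `!=`, `<`, `<=`, `>`, `>=`),
#' terminology subsumption (`$gt0003 is_a local::gt0102|stroke|`), existence
#' probes (`exists($gt0008)`), negation (`!`), conjunction (`&&`),
#' disjunction (`||`) and parentheses. Terms may add or subtract ISO 8601
#' durations to datetime terms (`$gt0010 + PT4H30M < currentDateTime`) and
#' add numeric terms (used by the score-summation rule). Actions are
#' assignments to output elements: `$gt0016=true`,
#' `$gt0021=SNOMED-CT::24099007|Oxygen|`, or an additive numeric expression.
#'
#' Operator precedence, loosest to tightest: `||`, `&&`, `!`,
#' comparison/`is_a`, additive `+`/`-`, primary. A bare `=` is assignment and
#' is only legal when parsing in action position; equality in a condition is
#' written `==`.
#'
#' @param text The expression source text.
#' @param role `"when"` to parse a condition, `"then"` to parse an action.
#' @return An AST node (a nested named list; the `node` field names the
#'   construct). `deparse_expr()` maps an AST back to canonical source text;
#'   parsing its output reproduces the AST.
#' @examples
#' parse_expression("$gt0008>25")
#' parse_expression("$gt0016=true", role = "then")
#' @export
parse_expression <- function(text, role = c("when", "then")) {
  role <- match.arg(role)
  toks <- expr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$pos <- 1L
  peek <- function() {
    if (st$pos > length(toks)) list(type = "eof", text = "<end>", col = nchar(text) + 1L)
    else toks[[st$pos]]
  }
  advance <- function() { t <- peek(); st$pos <- st$pos + 1L; t }
  fail <- function(t, msg) {
    stop(sprintf("syntax error at column %d in %s-expression '%s': %s (saw '%s')",
                 t$col, role, text, msg, t$text), call. = FALSE)
  }

  parse_term <- function() {
    t <- advance()
    lhs <- if (t$type == "gtref") {
      list(node = "gt_ref", code = sub("^\\$", "", t$text))
    } else if (t$type == "number") {
      list(node = "number", value = as.numeric(t$text))
    } else if (t$text == "-" && peek()$type == "number") {
      list(node = "number", value = -as.numeric(advance()$text))
    } else if (t$type == "duration") {
      list(node = "duration", value = t$text)
    } else if (t$type == "string") {
      list(node = "string", value = unquote_odin_string(t$text))
    } else if (t$type == "bool") {
      list(node = "boolean", value = identical(t$text, "true"))
    } else if (t$type == "coded") {
      parse_coded_token(t$text)
    } else if (t$type == "ident" && t$text == "currentDateTime") {
      list(node = "current_datetime")
    } else {
      fail(t, "expected a term")
    }
    while (peek()$text %in% c("+", "-") && peek()$type == "op") {
      op <- advance()$text
      nxt <- peek()
      rhs <- parse_term_atom(nxt, fail, advance)
      lhs <- list(node = "arith", op = op, lhs = lhs, rhs = rhs)
    }
    lhs
  }

  parse_term_atom <- function(t, fail, advance) {
    t <- advance()
    if (t$type == "gtref") return(list(node = "gt_ref", code = sub("^\\$", "", t$text)))
    if (t$type == "number") return(list(node = "number", value = as.numeric(t$text)))
    if (t$type == "duration") return(list(node = "duration", value = t$text))
    if (t$type == "ident" && t$text == "currentDateTime") {
      return(list(node = "current_datetime"))
    }
    fail(t, "expected a term after '+'/'-'")
  }

  parse_primary <- function() {
    t <- peek()
    if (t$text == "(" && t$type == "op") {
      advance()
      inner <- parse_or()
      if (peek()$text != ")") fail(peek(), "expected ')'")
      advance()
      return(inner)
    }
    if (t$type == "ident" && t$text == "exists") {
      advance()
      if (peek()$text != "(") fail(peek(), "expected '(' after exists")
      advance()
      ref <- advance()
      if (ref$type != "gtref") fail(ref, "exists() takes a $gt reference")
      if (peek()$text != ")") fail(peek(), "expected ')'")
      advance()
      return(list(node = "exists", code = sub("^\\$", "", ref$text)))
    }
    lhs <- parse_term()
    t <- peek()
    if (t$type == "ident" && t$text == "is_a") {
      advance()
      g <- advance()
      if (g$type != "coded") fail(g, "is_a takes a local::gtXXXX group reference")
      grp <- parse_coded_token(g$text)
      if (grp$system != "local") fail(g, "is_a group must be in the local system")
      return(list(node = "is_a", lhs = lhs, group = grp$code,
                  display = grp$display))
    }
    if (t$type == "op" && t$text %in% c("==", "!=", "<", "<=", ">", ">=")) {
      advance()
      rhs <- parse_term()
      return(list(node = "comparison", op = t$text, lhs = lhs, rhs = rhs))
    }
    if (t$type == "op" && t$text == "=") {
      fail(t, "'=' is assignment; use '==' for equality in a condition")
    }
    fail(t, "expected a comparison, is_a or exists")
  }

  parse_not <- function() {
    if (peek()$text == "!" && peek()$type == "op") {
      advance()
      return(list(node = "not", x = parse_not()))
    }
    parse_primary()
  }

  parse_and <- function() {
    args <- list(parse_not())
    while (peek()$text == "&&") {
      advance()
      args[[length(args) + 1L]] <- parse_not()
    }
    if (length(args) == 1L) args[[1]] else list(node = "and", args = args)
  }

  parse_or <- function() {
    args <- list(parse_and())
    while (peek()$text == "||") {
      advance()
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) args[[1]] else list(node = "or", args = args)
  }

  out <- if (role == "then") {
    t <- advance()
    if (t$type != "gtref") fail(t, "an action assigns to a $gt reference")
    target <- sub("^\\$", "", t$text)
    eq <- advance()
    if (eq$text != "=" || eq$type != "op") fail(eq, "expected '=' in action")
    value <- parse_term()
    list(node = "assign", target = target, value = value)
  } else {
    parse_or()
  }
  if (peek()$type != "eof") fail(peek(), "trailing content")
  out
}

parse_coded_token <- function(s) {
  m <- regmatches(s, regexec("^([A-Za-z][A-Za-z0-9_-]*)::([A-Za-z0-9._-]+)(\\|([^|]*)\\|)?$",
                             s))[[1]]
  list(node = "coded", system = m[2], code = m[3],
       display = if (nzchar(m[4])) m[5] else "")
}

EXPR_TOKEN_REGEX <- paste0(
  "(\"(?:[^\"\\\\]|\\\\.)*\")",                                  # string
  "|(\\$gt\\d+)",                                                # gt reference
  "|([A-Za-z][A-Za-z0-9_-]*::[A-Za-z0-9._-]+(?:\\|[^|]*\\|)?)",  # coded literal
  "|(==|!=|<=|>=|&&|\\|\\|)",                                    # two-char ops
  "|(\\d+(?:\\.\\d+)?)",                                         # number
  "|([A-Za-z_][A-Za-z0-9_]*)",                                   # ident
  "|([<>=!+()-])"                                                # one-char ops
)

expr_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- gregexpr(EXPR_TOKEN_REGEX, text, perl = TRUE)[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  if (starts[1] == -1L) { starts <- integer(); lens <- integer() }
  covered <- rep(FALSE, nchar(text))
  for (i in seq_along(starts)) covered[seq(starts[i], length.out = lens[i])] <- TRUE
  chars <- strsplit(text, "")[[1]]
  stray <- which(!covered & !grepl("^\\s$", chars))
  if (length(stray)) {
    stop(sprintf("syntax error at column %d in '%s': unexpected character '%s'",
                 stray[1], text, chars[stray[1]]), call. = FALSE)
  }
  toks <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    s <- substr(text, starts[i], starts[i] + lens[i] - 1L)
    type <- if (startsWith(s, "\"")) "string"
      else if (grepl("^\\$gt", s)) "gtref"
      else if (grepl("::", s, fixed = TRUE)) "coded"
      else if (grepl("^\\d", s)) "number"
      else if (s %in% c("true", "false")) "bool"
      else if (grepl("^[A-Za-z_]", s)) {
        if (grepl("^P", s) && !inherits(try(parse_iso_duration(s), silent = TRUE),
                                        "try-error")) "duration" else "ident"
      } else "op"
    toks[[i]] <- list(type = type, text = s, col = starts[i])
  }
  toks
}

#' @rdname parse_expression
#' @param ast An AST node produced by `parse_expression()`.
#' @export
deparse_expr <- function(ast) {
  paren_if <- function(s, need) if (need) paste0("(", s, ")") else s
  dep <- function(x, parent = "") {
    switch(x$node,
      gt_ref = paste0("$", x$code),
      number = format(x$value, scientific = FALSE, trim = TRUE, digits = 15),
      duration = x$value,
      string = quote_odin_string(x$value),
      boolean = if (x$value) "true" else "false",
      coded = paste0(x$system, "::", x$code,
                     if (nzchar(x$display)) paste0("|", x$display, "|") else ""),
      current_datetime = "currentDateTime",
      arith = paste0(dep(x$lhs), x$op, dep(x$rhs)),
      comparison = paste0(dep(x$lhs), x$op, dep(x$rhs)),
      is_a = paste0(dep(x$lhs), " is_a local::", x$group,
                    if (nzchar(x$display)) paste0("|", x$display, "|") else ""),
      exists = paste0("exists($", x$code, ")"),
      not = paste0("!", paren_if(dep(x$x, "not"),
                                 x$x$node %in% c("and", "or"))),
      and = paste(vapply(x$args, function(a) {
        paren_if(dep(a, "and"), a$node == "or")
      }, character(1)), collapse = " && "),
      or = paste(vapply(x$args, function(a) dep(a, "or"), character(1)),
                 collapse = " || "),
      assign = paste0("$", x$target, "=", dep(x$value)),
      stop("unknown AST node: ", x$node, call. = FALSE))
  }
  dep(ast)
}

# gt-codes referenced by an AST (including assignment targets when
# include_target is TRUE).
expr_gt_refs <- function(ast, include_target = TRUE) {
  out <- character()
  walk <- function(x) {
    if (!is.list(x) || is.null(x$node)) return()
    if (x$node == "gt_ref") out <<- c(out, x$code)
    if (x$node == "exists") out <<- c(out, x$code)
    if (x$node == "assign") {
      if (include_target) out <<- c(out, x$target)
      walk(x$value)
    }
    for (f in c("lhs", "rhs", "x", "value")) if (!is.null(x[[f]])) walk(x[[f]])
    if (!is.null(x$args)) for (a in x$args) walk(a)
  }
  walk(ast)
  unique(out)
}

# Term-group codes referenced through is_a.
expr_group_refs <- function(ast) {
  out <- character()
  walk <- function(x) {
    if (!is.list(x) || is.null(x$node)) return()
    if (x$node == "is_a") out <<- c(out, x$group)
    for (f in c("lhs", "rhs", "x", "value")) if (!is.null(x[[f]])) walk(x[[f]])
    if (!is.null(x$args)) for (a in x$args) walk(a)
  }
  walk(ast)
  unique(out)
}
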