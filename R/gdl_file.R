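#' Guidelines: bindings, rules and terminology sections
#'
#' A guideline packages three things:
#'
#' * **archetype bindings** — guideline-local codes (`gt0003`) assigned to
#'   archetype elements, each marked `input` (read from the patient case) or
#'   `output` (written by rule actions);
#' * **rules** — `when`/`then` pairs; the `when` list is an implicit
#'   conjunction of conditions, the `then` list a sequence of assignments;
#' * **terminology** — term groups (named code sets, possibly bound in
#'   several code systems at once) referenced by `is_a` conditions.
#'
#' Guideline files use the same `key = <value>` dialect as case files, with
#' four sections: `definitions` (bindings), `term_groups` (group displays),
#' `rules` and `terminology` (per-system code bindings). Serializing and
#' re-parsing a guideline reproduces it structurally.
#'
#' @name guideline
NULL

#' @rdname guideline
#' @param gt_code Guideline-local code (`gtXXXX`).
#' @param archetype_id,path The bound archetype element.
#' @param direction `"input"` or `"output"`.
#' @export
gdl_binding <- function(gt_code, archetype_id, path, direction = c("input", "output")) {
  direction <- match.arg(direction)
  stopifnot(grepl("^gt[0-9]+$", gt_code), is.character(archetype_id),
            nzchar(archetype_id))
  if (!is_valid_path(path)) stop("malformed element path: ", path, call. = FALSE)
  structure(list(gt_code = gt_code, archetype_id = archetype_id, path = path,
                 direction = direction),
            class = "strokecds_binding")
}

#' @rdname guideline
#' @param rule_id Rule identifier, unique within the guideline.
#' @param when Character vector of condition expressions (implicit
#'   conjunction; may be empty, which reads as always-true).
#' @param then Character vector of assignment expressions; at least one.
#' @param priority Integer; higher priorities are evaluated first.
#' @export
gdl_rule <- function(rule_id, when = character(), then, priority = 0L) {
  stopifnot(is.character(rule_id), length(rule_id) == 1L, nzchar(rule_id))
  if (!length(then)) stop("rule ", rule_id, " has an empty then-part", call. = FALSE)
  structure(list(
    rule_id = rule_id,
    priority = as.integer(priority),
    when = lapply(when, parse_expression, role = "when"),
    then = lapply(then, parse_expression, role = "then")),
    class = "strokecds_rule")
}

#' @rdname guideline
#' @param guideline_id,description Identifier and free-text description.
#' @param bindings List of [gdl_binding()]s.
#' @param term_groups List of [term_group()]s.
#' @param rules List of [gdl_rule()]s.
#' @export
new_guideline <- function(guideline_id, description = "", bindings = list(),
                          term_groups = list(), rules = list()) {
  stopifnot(is.character(guideline_id), length(guideline_id) == 1L,
            nzchar(guideline_id))
  gt <- vapply(bindings, `[[`, character(1), "gt_code")
  if (anyDuplicated(gt)) {
    stop("duplicate gt-code binding: ", gt[duplicated(gt)][1], call. = FALSE)
  }
  names(bindings) <- gt
  gcodes <- vapply(term_groups, `[[`, character(1), "group_code")
  if (anyDuplicated(gcodes)) stop("duplicate term group code", call. = FALSE)
  names(term_groups) <- gcodes
  rids <- vapply(rules, `[[`, character(1), "rule_id")
  if (anyDuplicated(rids)) {
    stop("duplicate rule id: ", rids[duplicated(rids)][1], call. = FALSE)
  }
  names(rules) <- rids
  structure(list(guideline_id = guideline_id, description = description,
                 bindings = bindings, term_groups = term_groups, rules = rules),
            class = "strokecds_guideline")
}

#' @export
print.strokecds_guideline <- function(x, ...) {
  cat("<guideline> ", x$guideline_id, ": ", length(x$bindings), " bindings, ",
      length(x$rules), " rules, ", length(x$term_groups), " term groups\n",
      sep = "")
  invisible(x)
}

#' Serialize or parse a guideline file
#'
#' @param g A guideline.
#' @param path Target/source file path; `NULL` to work on strings.
#' @param text Document text (readers only).
#' @return `serialize_guideline()` the text (or `path` invisibly);
#'   `parse_guideline()` a guideline object.
#' @export
serialize_guideline <- function(g, path = NULL) {
  stopifnot(inherits(g, "strokecds_guideline"))
  sc <- function(type, value) list(kind = "scalar", tag = NULL,
                                   scalar_type = type, value = value)
  strlist <- function(values) {
    if (length(values) == 1L) sc("string", values[[1]])
    else list(kind = "list", tag = NULL,
              values = lapply(values, function(v) sc("string", v)))
  }
  bind_nodes <- lapply(g$bindings, function(b) {
    list(kind = "block", tag = NULL, attrs = list(
      archetype_id = sc("string", b$archetype_id),
      path = sc("string", b$path),
      direction = sc("string", b$direction)))
  })
  group_nodes <- lapply(g$term_groups, function(tg) sc("string", tg$display))
  rule_nodes <- lapply(g$rules, function(r) {
    attrs <- list(priority = sc("number", r$priority))
    if (length(r$when)) attrs$when <- strlist(lapply(r$when, deparse_expr))
    attrs$then <- strlist(lapply(r$then, deparse_expr))
    list(kind = "block", tag = NULL, attrs = attrs)
  })
  systems <- unique(unlist(lapply(g$term_groups, function(tg) names(tg$bindings))))
  term_nodes <- list()
  for (sys in systems) {
    per_group <- list()
    for (tg in g$term_groups) {
      codes <- tg$bindings[[sys]]
      if (!is.null(codes) && length(codes)) {
        per_group[[tg$group_code]] <- strlist(as.list(codes))
      }
    }
    term_nodes[[sys]] <- list(kind = "block", tag = NULL, attrs = per_group)
  }
  tree <- list(kind = "block", tag = NULL, attrs = list(
    guideline_id = sc("string", g$guideline_id),
    description = sc("string", g$description),
    definitions = list(kind = "block", tag = NULL, attrs = bind_nodes),
    term_groups = list(kind = "block", tag = NULL, attrs = group_nodes),
    rules = list(kind = "block", tag = NULL, attrs = rule_nodes),
    terminology = list(kind = "block", tag = NULL, attrs = term_nodes)))
  txt <- paste0(odin_serialize(tree), "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(path)
}

#' @rdname serialize_guideline
#' @export
parse_guideline <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  tree <- odin_parse(text)
  defs <- odin_attr(tree, "definitions", required = FALSE)
  bindings <- list()
  if (!is.null(defs)) {
    bindings <- lapply(names(defs$attrs), function(code) {
      b <- defs$attrs[[code]]
      gdl_binding(code, odin_scalar_value(b, "archetype_id"),
                  odin_scalar_value(b, "path"),
                  odin_scalar_value(b, "direction"))
    })
  }
  groups_node <- odin_attr(tree, "term_groups", required = FALSE)
  displays <- if (is.null(groups_node)) list() else
    lapply(groups_node$attrs, `[[`, "value")
  term_node <- odin_attr(tree, "terminology", required = FALSE)
  group_bindings <- list()  # group code -> system -> codes
  if (!is.null(term_node)) {
    for (sys in names(term_node$attrs)) {
      for (gcode in names(term_node$attrs[[sys]]$attrs)) {
        codes <- unlist(odin_list_values(term_node$attrs[[sys]], gcode))
        group_bindings[[gcode]][[sys]] <- codes
      }
    }
  }
  all_groups <- union(names(displays), names(group_bindings))
  term_groups <- lapply(all_groups, function(gcode) {
    term_group(gcode,
               display = if (!is.null(displays[[gcode]])) displays[[gcode]] else gcode,
               bindings = group_bindings[[gcode]])
  })
  rules_node <- odin_attr(tree, "rules", required = FALSE)
  rules <- list()
  if (!is.null(rules_node)) {
    rules <- lapply(names(rules_node$attrs), function(rid) {
      rn <- rules_node$attrs[[rid]]
      when_node <- odin_attr(rn, "when", required = FALSE)
      when <- if (is.null(when_node)) character() else
        unlist(odin_list_values(rn, "when"))
      gdl_rule(rid, when = when, then = unlist(odin_list_values(rn, "then")),
               priority = odin_scalar_value(rn, "priority"))
    })
  }
  new_guideline(odin_scalar_value(tree, "guideline_id"),
                description = odin_scalar_value(tree, "description", required = FALSE) %||% "",
                bindings = bindings, term_groups = term_groups, rules = rules)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The kind a term evaluates to, given bindings and schemas:
# "number", "boolean", "text", "coded", "date_time", "duration", or NA.
term_kind <- function(term, g, registry) {
  switch(term$node,
    number = "number",
    boolean = "boolean",
    string = "text",
    coded = "coded",
    duration = "duration",
    current_datetime = "date_time",
    gt_ref = {
      b <- g$bindings[[term$code]]
      if (is.null(b)) return(NA_character_)
      schema <- tryCatch(get_schema(registry, b$archetype_id),
                         error = function(e) NULL)
      def <- if (is.null(schema)) NULL else schema$elements[[b$path]]
      if (is.null(def)) return(NA_character_)
      switch(def$kind, count = "number", quantity = "number",
             boolean = "boolean", text = "text", coded_text = "coded",
             date_time = "date_time", duration = "duration")
    },
    arith = {
      lk <- term_kind(term$lhs, g, registry)
      rk <- term_kind(term$rhs, g, registry)
      if (is.na(lk) || is.na(rk)) NA_character_
      else if (lk == "date_time" && rk == "duration") "date_time"
      else if (lk == "duration" && rk == "duration") "duration"
      else if (lk == "number" && rk == "number") "number"
      else "invalid"
    },
    NA_character_)
}

#' Validate a guideline against schemas and terminology
#'
#' Checks that every binding resolves to a registered archetype element, that
#' every rule reference is bound, that assignment targets are output-bound,
#' that `is_a` groups exist with at least one binding whose codes are present
#' in the terminology store, and that comparisons are type-compatible.
#'
#' @param g A guideline.
#' @param registry A [schema_registry()].
#' @param store A [terminology_store()].
#' @return Tibble of violations (`where`, `problem`, `detail`); zero rows
#'   means the guideline is executable.
#' @export
validate_guideline <- function(g, registry, store) {
  stopifnot(inherits(g, "strokecds_guideline"))
  v <- list()
  note <- function(where, problem, detail) {
    v[[length(v) + 1L]] <<- tibble::tibble(where = where, problem = problem,
                                           detail = detail)
  }
  for (b in g$bindings) {
    schema <- tryCatch(get_schema(registry, b$archetype_id), error = function(e) NULL)
    if (is.null(schema)) {
      note(b$gt_code, "unknown_archetype", b$archetype_id)
    } else if (is.null(schema$elements[[b$path]])) {
      note(b$gt_code, "unknown_path", paste0(b$archetype_id, " ", b$path))
    }
  }
  for (tg in g$term_groups) {
    if (!length(tg$bindings)) {
      note(tg$group_code, "empty_group", "term group binds no codes")
      next
    }
    for (sys in names(tg$bindings)) {
      known <- tryCatch(names(get_system(store, sys)$concepts),
                        error = function(e) character())
      missing <- setdiff(tg$bindings[[sys]], known)
      if (length(missing)) {
        note(tg$group_code, "unknown_code",
             paste0(sys, ": ", paste(missing, collapse = ", ")))
      }
    }
  }
  comparable <- function(lk, rk) {
    if (is.na(lk) || is.na(rk)) return(TRUE)  # reported separately
    if (lk == "invalid" || rk == "invalid") return(FALSE)
    lk == rk
  }
  check_cond <- function(cond, rid) {
    walk <- function(x) {
      if (x$node %in% c("and", "or")) { for (a in x$args) walk(a); return() }
      if (x$node == "not") { walk(x$x); return() }
      if (x$node == "comparison") {
        lk <- term_kind(x$lhs, g, registry)
        rk <- term_kind(x$rhs, g, registry)
        if (!comparable(lk, rk)) {
          note(rid, "type_mismatch",
               paste0(deparse_expr(x), " compares ", lk, " with ", rk))
        } else if (!is.na(lk) && lk %in% c("boolean", "text", "coded") &&
                   !x$op %in% c("==", "!=")) {
          note(rid, "type_mismatch",
               paste0(deparse_expr(x), ": ", lk, " values only support == and !="))
        }
      }
      if (x$node == "is_a") {
        tg <- g$term_groups[[x$group]]
        if (is.null(tg)) {
          note(rid, "unknown_group", x$group)
        } else if (!length(tg$bindings)) {
          note(rid, "empty_group", x$group)
        }
        lk <- term_kind(x$lhs, g, registry)
        if (!is.na(lk) && lk != "coded") {
          note(rid, "type_mismatch", paste0("is_a applied to ", lk, " value"))
        }
      }
    }
    walk(cond)
  }
  for (r in g$rules) {
    refs <- unique(unlist(c(lapply(r$when, expr_gt_refs),
                            lapply(r$then, expr_gt_refs))))
    unbound <- setdiff(refs, names(g$bindings))
    if (length(unbound)) {
      note(r$rule_id, "unbound_gt_code", paste(unbound, collapse = ", "))
    }
    for (a in r$then) {
      b <- g$bindings[[a$target]]
      if (!is.null(b) && b$direction != "output") {
        note(r$rule_id, "assign_to_input", a$target)
      }
      vk <- term_kind(a$value, g, registry)
      tk <- term_kind(list(node = "gt_ref", code = a$target), g, registry)
      if (!is.na(vk) && !is.na(tk) && vk != "invalid" && vk != tk) {
        note(r$rule_id, "type_mismatch",
             paste0("assigning ", vk, " to ", tk, " element ", a$target))
      }
    }
    for (w in r$when) check_cond(w, r$rule_id)
  }
  if (length(v)) dplyr::bind_rows(v) else {
    tibble::tibble(where = character(), problem = character(), detail = character())
  }
}

# Structural equality of two guidelines (ids, bindings, groups, rules with
# canonically deparsed expressions).
guideline_equal <- function(a, b) {
  canon <- function(g) {
    list(id = g$guideline_id,
         bindings = lapply(g$bindings[sort(names(g$bindings))], unclass),
         groups = lapply(g$term_groups[sort(names(g$term_groups))], function(tg) {
           list(code = tg$group_code, display = tg$display,
                bindings = lapply(tg$bindings[sort(names(tg$bindings))],
                                  function(x) sort(unname(x))))
         }),
         rules = lapply(g$rules[sort(names(g$rules))], function(r) {
           list(id = r$rule_id, priority = r$priority,
                when = vapply(r$when, deparse_expr, character(1)),
                then = vapply(r$then, deparse_expr, character(1)))
         }))
  }
  identical(canon(a), canon(b))
}
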