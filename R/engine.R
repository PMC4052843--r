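#' Evaluate a guideline against a patient case
#'
#' The engine binds rule inputs to entry instances, evaluates conditions
#' under three-valued (Kleene) logic, fires rules whose when-part is fully
#' true on some candidate tuple, applies their assignments to a working
#' memory of output values, and repeats until a fixpoint: one full pass in
#' which no assignment changes any value. Rules are considered in descending
#' priority, then declaration order, so evaluation is deterministic; the
#' shipped content is stratified (item rules before summation, set-true
#' before guarded set-false), which makes the fixpoint independent of
#' declaration order.
#'
#' Missing data never silently counts as false: a condition touching an
#' absent value is *unknown* and the rule does not fire. Output elements
#' whose governing rules could not be decided for lack of data are reported
#' as indeterminate, distinct from an explicit false.
#'
#' @name engine
NULL

# Kleene connectives over TRUE/FALSE/NA.
k_and <- function(vals) {
  if (any(vapply(vals, isFALSE, logical(1)))) return(FALSE)
  if (any(is.na(unlist(vals)))) return(NA)
  TRUE
}
k_or <- function(vals) {
  if (any(vapply(vals, isTRUE, logical(1)))) return(TRUE)
  if (any(is.na(unlist(vals)))) return(NA)
  FALSE
}
k_not <- function(v) if (is.na(v)) NA else !v

#' Candidate entry tuples for a rule
#'
#' A rule reads its inputs from one entry instance per input archetype; the
#' candidate tuples are the cartesian product of the case's entries over the
#' archetypes the rule's input bindings touch (entries ordered by event
#' time). A rule with no input references has exactly one empty tuple; a
#' rule whose input archetype has no entries has none, so it can never fire.
#'
#' @param guideline A validated guideline.
#' @param case A [patient_case()].
#' @param rule_id A rule id; `NULL` returns a list over all rules.
#' @return A list of tuples (each a named list archetype id -> entry), or a
#'   named list of such lists when `rule_id` is `NULL`.
#' @export
bind_inputs <- function(guideline, case, rule_id = NULL) {
  if (is.null(rule_id)) {
    out <- lapply(names(guideline$rules), function(rid) {
      bind_inputs(guideline, case, rid)
    })
    names(out) <- names(guideline$rules)
    return(out)
  }
  rule <- guideline$rules[[rule_id]]
  if (is.null(rule)) stop("unknown rule: ", rule_id, call. = FALSE)
  refs <- unique(unlist(c(lapply(rule$when, expr_gt_refs),
                          lapply(rule$then, expr_gt_refs))))
  archetypes <- unique(vapply(
    Filter(Negate(is.null), lapply(refs, function(code) {
      b <- guideline$bindings[[code]]
      if (!is.null(b) && b$direction == "input") b$archetype_id else NULL
    })),
    identity, character(1)))
  if (!length(archetypes)) return(list(stats::setNames(list(), character())))
  pools <- lapply(archetypes, function(aid) entries_of(case, aid))
  if (any(!lengths(pools))) return(list())
  idx <- expand.grid(lapply(pools, seq_along), KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(idx)), function(i) {
    tuple <- lapply(seq_along(archetypes), function(j) pools[[j]][[idx[i, j]]])
    names(tuple) <- archetypes
    tuple
  })
}

# Resolve a gt reference to a data value, or NULL when absent.
# Inputs come from the candidate tuple; outputs from working memory.
resolve_ref <- function(code, ctx, tuple) {
  b <- ctx$guideline$bindings[[code]]
  if (is.null(b)) stop("unbound gt-code: ", code, call. = FALSE)
  if (b$direction == "output") return(ctx$wm[[code]])
  entry <- tuple[[b$archetype_id]]
  if (is.null(entry)) return(NULL)
  entry$elements[[b$path]]
}

# Evaluate a term to a value descriptor: list(kind, ...) mirroring data
# values, with plain literals as kind "number"/"text"/..., or NULL (unknown).
eval_term <- function(term, ctx, tuple) {
  switch(term$node,
    number = list(kind = "number", value = term$value),
    boolean = list(kind = "boolean", value = term$value),
    string = list(kind = "text", value = term$value),
    duration = list(kind = "duration", seconds = parse_iso_duration(term$value),
                    value = term$value),
    coded = list(kind = "coded_text", system = term$system, code = term$code,
                 display = term$display),
    current_datetime = list(kind = "date_time", value = ctx$now),
    gt_ref = {
      dv <- resolve_ref(term$code, ctx, tuple)
      if (is.null(dv)) NULL else unclass(dv)
    },
    arith = {
      a <- eval_term(term$lhs, ctx, tuple)
      b <- eval_term(term$rhs, ctx, tuple)
      if (is.null(a) || is.null(b)) return(NULL)
      sgn <- if (term$op == "+") 1 else -1
      if (a$kind == "date_time" && b$kind == "duration") {
        list(kind = "date_time", value = a$value + sgn * b$seconds)
      } else if (a$kind == "duration" && b$kind == "duration") {
        list(kind = "duration", seconds = a$seconds + sgn * b$seconds,
             value = NA_character_)
      } else if (numeric_kind(a) && numeric_kind(b)) {
        list(kind = "number", value = numeric_of(a) + sgn * numeric_of(b))
      } else {
        stop("cannot apply ", term$op, " to ", a$kind, " and ", b$kind,
             call. = FALSE)
      }
    },
    stop("not a term: ", term$node, call. = FALSE))
}

numeric_kind <- function(v) v$kind %in% c("number", "count", "quantity")
numeric_of <- function(v) switch(v$kind, number = v$value, count = v$value,
                                 quantity = v$magnitude)

compare_values <- function(op, a, b) {
  if (numeric_kind(a) && numeric_kind(b)) {
    x <- numeric_of(a); y <- numeric_of(b)
  } else if (a$kind == "date_time" && b$kind == "date_time") {
    x <- as.numeric(a$value); y <- as.numeric(b$value)
  } else if (a$kind == "duration" && b$kind == "duration") {
    x <- a$seconds; y <- b$seconds
  } else if (a$kind %in% c("text", "coded_text") &&
             b$kind %in% c("text", "coded_text") && op %in% c("==", "!=")) {
    same <- if (a$kind == "coded_text" && b$kind == "coded_text") {
      a$system == b$system && a$code == b$code
    } else if (a$kind == "text" && b$kind == "text") {
      a$value == b$value
    } else {
      # coded vs plain text falls back to the display/value strings
      txt <- function(v) if (v$kind == "text") v$value else v$display
      txt(a) == txt(b)
    }
    return(if (op == "==") same else !same)
  } else if (a$kind == "boolean" && b$kind == "boolean" && op %in% c("==", "!=")) {
    return(if (op == "==") a$value == b$value else a$value != b$value)
  } else {
    stop("cannot compare ", a$kind, " ", op, " ", b$kind, call. = FALSE)
  }
  switch(op, "==" = x == y, "!=" = x != y, "<" = x < y, "<=" = x <= y,
         ">" = x > y, ">=" = x >= y)
}

#' Evaluate one condition on one candidate tuple
#'
#' @param cond A condition AST from [parse_expression()].
#' @param ctx Evaluation context as built by [run_guideline()]: a list with
#'   `guideline`, `case`, `now` (the evaluation instant), `wm` (working
#'   memory of output values) and `store` (terminology).
#' @param tuple A candidate tuple from [bind_inputs()].
#' @return `TRUE`, `FALSE` or `NA` (unknown: some referenced value is
#'   absent).
#' @export
eval_condition <- function(cond, ctx, tuple = list()) {
  switch(cond$node,
    and = k_and(lapply(cond$args, eval_condition, ctx = ctx, tuple = tuple)),
    or = k_or(lapply(cond$args, eval_condition, ctx = ctx, tuple = tuple)),
    not = k_not(eval_condition(cond$x, ctx, tuple)),
    exists = !is.null(resolve_ref(cond$code, ctx, tuple)),
    is_a = {
      v <- eval_term(cond$lhs, ctx, tuple)
      if (is.null(v)) return(NA)
      if (v$kind != "coded_text") {
        stop("is_a applied to a non-coded value", call. = FALSE)
      }
      tg <- ctx$guideline$term_groups[[cond$group]]
      if (is.null(tg)) stop("unknown term group: ", cond$group, call. = FALSE)
      matches_group(dv_coded(v$system, v$code, v$display), tg, ctx$store)
    },
    comparison = {
      a <- eval_term(cond$lhs, ctx, tuple)
      b <- eval_term(cond$rhs, ctx, tuple)
      if (is.null(a) || is.null(b)) return(NA)
      compare_values(cond$op, a, b)
    },
    stop("not a condition: ", cond$node, call. = FALSE))
}

rule_when_value <- function(rule, ctx, tuple) {
  if (!length(rule$when)) return(TRUE)
  k_and(lapply(rule$when, eval_condition, ctx = ctx, tuple = tuple))
}

# Coerce an evaluated assignment value to the target element's declared kind.
coerce_output <- function(v, def, gt_code) {
  if (is.null(def)) stop("unknown output element for ", gt_code, call. = FALSE)
  switch(def$kind,
    count = {
      x <- numeric_of(v)
      if (is.null(x)) stop("cannot assign ", v$kind, " to count ", gt_code, call. = FALSE)
      dv_count(round(x))
    },
    quantity = dv_quantity(numeric_of(v), def$unit),
    boolean = dv_boolean(v$value),
    text = dv_text(if (v$kind == "coded_text") v$display else v$value),
    coded_text = dv_coded(v$system, v$code, v$display),
    date_time = dv_datetime(v$value),
    duration = dv_duration(v$value))
}

#' @rdname engine
#' @param guideline A guideline; validate with [validate_guideline()] first.
#' @param case A [patient_case()].
#' @param registry The schema registry (for output element kinds and units).
#' @param store The terminology store.
#' @param current_datetime The evaluation instant; defaults to the case's
#'   reference time, which anchors look-back windows to the care decision
#'   being audited rather than to wall-clock now.
#' @return An object of class `strokecds_result`: `outputs` (named list,
#'   gt-code to data value), `outputs_by_path` (tibble), `fired` (rule ids in
#'   firing order), `indeterminate` and `determinate_unset` (gt-codes of
#'   output elements never assigned, split by whether the lack is due to
#'   missing data or to all governing rules evaluating false), and
#'   `rule_status` (per-rule evaluation summary after fixpoint).
#' @export
run_guideline <- function(guideline, case, registry, store,
                          current_datetime = NULL) {
  stopifnot(inherits(guideline, "strokecds_guideline"),
            inherits(case, "strokecds_case"))
  now <- if (is.null(current_datetime)) case$reference_time
    else dv_datetime(current_datetime)$value
  ctx <- new.env(parent = emptyenv())
  ctx$guideline <- guideline
  ctx$case <- case
  ctx$now <- now
  ctx$store <- store
  ctx$wm <- list()
  ord <- order(-vapply(guideline$rules, `[[`, integer(1), "priority"),
               seq_along(guideline$rules))
  rules <- guideline$rules[ord]
  tuples_by_rule <- lapply(rules, function(r) bind_inputs(guideline, case, r$rule_id))
  output_def <- function(code) {
    b <- guideline$bindings[[code]]
    get_schema(registry, b$archetype_id)$elements[[b$path]]
  }

  fired <- character()
  max_pass <- length(rules) + 1L
  pass <- 0L
  repeat {
    pass <- pass + 1L
    if (pass > max_pass) {
      stop("no fixpoint after ", max_pass,
           " passes: rule set assigns in a cycle", call. = FALSE)
    }
    changed <- FALSE
    for (r in rules) {
      for (tuple in tuples_by_rule[[r$rule_id]]) {
        if (!isTRUE(rule_when_value(r, ctx, tuple))) next
        vals <- lapply(r$then, function(a) eval_term(a$value, ctx, tuple))
        if (any(vapply(vals, is.null, logical(1)))) next  # rhs not yet known
        applied <- FALSE
        for (k in seq_along(r$then)) {
          target <- r$then[[k]]$target
          new <- coerce_output(vals[[k]], output_def(target), target)
          old <- ctx$wm[[target]]
          if (is.null(old) || !dv_equal(old, new)) {
            ctx$wm[[target]] <- new
            changed <- TRUE
          }
          applied <- TRUE
        }
        if (applied && !r$rule_id %in% fired) {
          fired <- c(fired, r$rule_id)
        }
        break  # existential: first satisfying tuple decides
      }
    }
    if (!changed) break
  }

  # Post-fixpoint probe: classify rule evaluations so that unset outputs can
  # be told apart as "determinately not set" (all governing rules false on
  # real tuples) vs indeterminate (missing data). Only rules governing an
  # unset output need probing; the rest are summarised from the run.
  out_codes <- names(Filter(function(b) b$direction == "output",
                            guideline$bindings))
  governs <- lapply(rules, function(r) {
    vapply(r$then, `[[`, character(1), "target")
  })
  unset <- setdiff(out_codes, names(ctx$wm))
  needs_probe <- vapply(governs, function(tg) any(tg %in% unset), logical(1))
  status <- lapply(rules[needs_probe], function(r) {
    tuples <- tuples_by_rule[[r$rule_id]]
    vals <- lapply(tuples, function(tuple) rule_when_value(r, ctx, tuple))
    rhs_unknown <- any(vapply(seq_along(tuples), function(i) {
      isTRUE(vals[[i]]) && any(vapply(r$then, function(a) {
        is.null(eval_term(a$value, ctx, tuples[[i]]))
      }, logical(1)))
    }, logical(1)))
    tibble::tibble(
      rule_id = r$rule_id, priority = r$priority, n_tuples = length(tuples),
      any_true = any(vapply(vals, isTRUE, logical(1))),
      any_unknown = any(is.na(unlist(vals))) || rhs_unknown,
      fired = r$rule_id %in% fired)
  })
  rule_status <- dplyr::bind_rows(c(status, lapply(rules[!needs_probe], function(r) {
    tibble::tibble(rule_id = r$rule_id, priority = r$priority,
                   n_tuples = length(tuples_by_rule[[r$rule_id]]),
                   any_true = r$rule_id %in% fired, any_unknown = NA,
                   fired = r$rule_id %in% fired)
  })))

  classify <- function(code) {
    idx <- which(vapply(governs, function(tg) code %in% tg, logical(1)))
    if (!length(idx)) return("indeterminate")  # no rule can ever set it
    st <- rule_status[match(names(rules)[idx], rule_status$rule_id), ]
    if (all(st$n_tuples > 0L) && !any(st$any_unknown) && !any(st$any_true)) {
      "determinate"
    } else {
      "indeterminate"
    }
  }
  cls <- vapply(unset, classify, character(1))
  outputs <- ctx$wm
  paths <- dplyr::bind_rows(lapply(names(outputs), function(code) {
    b <- guideline$bindings[[code]]
    tibble::tibble(gt_code = code, archetype_id = b$archetype_id,
                   path = b$path, kind = outputs[[code]]$kind,
                   value = format_dv(outputs[[code]]))
  }))
  structure(list(
    guideline_id = guideline$guideline_id,
    outputs = outputs,
    outputs_by_path = paths,
    fired = fired,
    indeterminate = unset[cls == "indeterminate"],
    determinate_unset = unset[cls == "determinate"],
    rule_status = rule_status,
    current_datetime = now),
    class = "strokecds_result")
}

#' @export
print.strokecds_result <- function(x, ...) {
  cat("<engine result> ", x$guideline_id, ": ", length(x$fired),
      " rules fired, ", length(x$outputs), " outputs set",
      if (length(x$indeterminate)) paste0(", ", length(x$indeterminate),
                                          " indeterminate") else "",
      "\n", sep = "")
  invisible(x)
}

#' Read a boolean output flag from an engine result
#'
#' @param result A `strokecds_result`.
#' @param gt_code Output binding code.
#' @return `TRUE`/`FALSE` when set, `NA` when the flag is indeterminate, and
#'   `FALSE` when determinately unset (all governing rules evaluated false).
#' @export
flag_value <- function(result, gt_code) {
  v <- result$outputs[[gt_code]]
  if (!is.null(v)) {
    if (v$kind != "boolean") stop(gt_code, " is not a boolean output", call. = FALSE)
    return(v$value)
  }
  if (gt_code %in% result$determinate_unset) return(FALSE)
  NA
}

#' Tidy an engine result
#'
#' @param x A `strokecds_result`.
#' @param ... Unused.
#' @return Tibble of set outputs (`gt_code`, `archetype_id`, `path`, `kind`,
#'   `value`).
#' @method tidy strokecds_result
#' @export
tidy.strokecds_result <- function(x, ...) {
  x$outputs_by_path
}
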