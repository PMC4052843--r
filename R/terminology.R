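#' Code systems, subsumption and term groups
#'
#' A terminology store holds one or more code systems (SNOMED CT, ICD-10,
#' ATC and the archetype-local `"local"` system). Each system is a set of
#' concepts with displays and parent links forming a directed acyclic graph;
#' [is_a()] answers subsumption queries ("is this code a kind of that
#' code?"), the relation the guideline dialect's `is_a` operator uses for
#' diagnosis-set membership.
#'
#' A term group is a guideline-local named set of codes, possibly drawn from
#' several systems at once (e.g. a "stroke" group bound to both ICD-10 I64
#' and SNOMED CT 230690007); [matches_group()] tests whether a coded value
#' falls under any code bound for its system.
#'
#' @name terminology
NULL

#' Construct a code system
#'
#' @param system_id System identifier, e.g. `"SNOMED-CT"`, `"ICD10"`,
#'   `"ATC"` or `"local"`.
#' @param concepts Named character vector: names are codes, values displays.
#' @param parents Named list mapping a code to a character vector of parent
#'   codes. All codes must exist in `concepts` and the graph must be acyclic.
#' @return An object of class `strokecds_codesystem`.
#' @export
code_system <- function(system_id, concepts = character(), parents = list()) {
  stopifnot(is.character(system_id), length(system_id) == 1L, nzchar(system_id))
  if (length(concepts) && (is.null(names(concepts)) || any(!nzchar(names(concepts))))) {
    stop("concepts must be a named character vector (code -> display)", call. = FALSE)
  }
  if (anyDuplicated(names(concepts))) {
    stop("duplicate concept codes in ", system_id, call. = FALSE)
  }
  for (code in names(parents)) {
    if (!code %in% names(concepts)) {
      stop("parent link from unknown code ", code, " in ", system_id, call. = FALSE)
    }
    missing <- setdiff(parents[[code]], names(concepts))
    if (length(missing)) {
      stop("dangling parent(s) of ", code, " in ", system_id, ": ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  sys <- structure(list(system_id = system_id, concepts = concepts,
                        parents = parents),
                   class = "strokecds_codesystem")
  cyc <- find_cycle(sys)
  if (!is.null(cyc)) {
    stop("cycle in parent graph of ", system_id, ": ",
         paste(cyc, collapse = " -> "), call. = FALSE)
  }
  sys
}

# Depth-first cycle detection; returns one offending path or NULL.
find_cycle <- function(sys) {
  state <- new.env(parent = emptyenv())  # "open" / "done"
  walk <- function(code, path) {
    s <- state[[code]]
    if (identical(s, "done")) return(NULL)
    if (identical(s, "open")) return(c(path, code))
    state[[code]] <- "open"
    for (p in sys$parents[[code]]) {
      hit <- walk(p, c(path, code))
      if (!is.null(hit)) return(hit)
    }
    state[[code]] <- "done"
    NULL
  }
  for (code in names(sys$parents)) {
    hit <- walk(code, character())
    if (!is.null(hit)) return(hit)
  }
  NULL
}

#' Assemble a terminology store
#'
#' @param systems List of [code_system()] objects.
#' @return An object of class `strokecds_terminology`.
#' @export
terminology_store <- function(systems = list()) {
  ok <- vapply(systems, inherits, logical(1), "strokecds_codesystem")
  if (length(systems) && !all(ok)) stop("systems must be code_system()s", call. = FALSE)
  ids <- vapply(systems, `[[`, character(1), "system_id")
  if (anyDuplicated(ids)) stop("duplicate system ids", call. = FALSE)
  names(systems) <- ids
  structure(list(systems = systems), class = "strokecds_terminology")
}

#' @export
print.strokecds_terminology <- function(x, ...) {
  cat("<terminology store>\n")
  for (s in x$systems) {
    cat("  ", s$system_id, ": ", length(s$concepts), " concepts\n", sep = "")
  }
  invisible(x)
}

get_system <- function(store, system_id) {
  s <- store$systems[[system_id]]
  if (is.null(s)) stop("unknown code system: ", system_id, call. = FALSE)
  s
}

#' Subsumption query
#'
#' `is_a(store, system_id, code, ancestor_code)` is `TRUE` iff `code` equals
#' `ancestor_code` or reaches it through parent links (reflexive-transitive
#' closure of the is-a graph).
#'
#' @param store A [terminology_store()].
#' @param system_id Code system identifier.
#' @param code,ancestor_code Codes; both must be registered in the system.
#' @return `TRUE` or `FALSE`.
#' @export
is_a <- function(store, system_id, code, ancestor_code) {
  sys <- get_system(store, system_id)
  for (c in c(code, ancestor_code)) {
    if (!c %in% names(sys$concepts)) {
      stop("unknown code in ", system_id, ": ", c, call. = FALSE)
    }
  }
  frontier <- code
  seen <- character()
  while (length(frontier)) {
    if (ancestor_code %in% frontier) return(TRUE)
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(sys$parents[frontier], use.names = FALSE)),
                        seen)
  }
  FALSE
}

#' Define a term group
#'
#' @param group_code Guideline-local group code (`gtXXXX` by convention).
#' @param display Human-readable label, e.g. `"stroke"`.
#' @param bindings Named list mapping a system id to a character vector of
#'   codes bound for that system; at least one binding is required.
#' @return An object of class `strokecds_termgroup`.
#' @export
term_group <- function(group_code, display, bindings) {
  stopifnot(is.character(group_code), length(group_code) == 1L, nzchar(group_code),
            is.character(display), length(display) == 1L)
  if (!length(bindings) || is.null(names(bindings)) ||
      any(!nzchar(names(bindings)))) {
    stop("term group ", group_code, " needs at least one named binding",
         call. = FALSE)
  }
  structure(list(group_code = group_code, display = display,
                 bindings = bindings),
            class = "strokecds_termgroup")
}

#' Test a coded value against a term group
#'
#' `TRUE` iff the value's code is subsumed by (is a kind of) any code the
#' group binds for the value's code system. A system with no binding in the
#' group yields `FALSE`: membership can only be established through an
#' explicit binding.
#'
#' @param value A [dv_coded()] value.
#' @param group A [term_group()].
#' @param store A [terminology_store()] covering the value's system.
#' @return `TRUE` or `FALSE`.
#' @export
matches_group <- function(value, group, store) {
  stopifnot(inherits(value, "dv_coded_text"), inherits(group, "strokecds_termgroup"))
  bound <- group$bindings[[value$system]]
  if (is.null(bound) || !length(bound)) return(FALSE)
  sys <- get_system(store, value$system)
  if (!value$code %in% names(sys$concepts)) return(FALSE)
  for (anc in bound) {
    if (anc %in% names(sys$concepts) && is_a(store, value$system, value$code, anc)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Load a terminology store from table files
#'
#' Each code system is one tab-separated file with columns `code`, `display`,
#' `parents` (a comma-separated list of parent codes, empty for roots). The
#' file name (without extension) is the system id, with `_` read as `-` so
#' that `SNOMED_CT.tsv` loads as system `"SNOMED-CT"`. Acyclicity and parent
#' resolution are verified on load.
#'
#' @param paths Character vector of file paths, or a directory containing
#'   `.tsv` files.
#' @return A [terminology_store()].
#' @export
load_terminology <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.tsv$", full.names = TRUE)
  }
  systems <- lapply(paths, function(p) {
    system_id <- gsub("_", "-", sub("\\.tsv$", "", basename(p)))
    tab <- utils::read.delim(p, colClasses = "character", stringsAsFactors = FALSE)
    need <- c("code", "display", "parents")
    if (!all(need %in% names(tab))) {
      stop("terminology file ", p, " must have columns code, display, parents",
           call. = FALSE)
    }
    concepts <- stats::setNames(tab$display, tab$code)
    tab$parents[is.na(tab$parents)] <- ""
    parents <- list()
    for (i in seq_len(nrow(tab))) {
      ps <- trimws(strsplit(tab$parents[i], ",", fixed = TRUE)[[1]])
      ps <- ps[nzchar(ps)]
      if (length(ps)) parents[[tab$code[i]]] <- ps
    }
    code_system(system_id, concepts, parents)
  })
  terminology_store(systems)
}
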