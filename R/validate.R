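# Semantic validation: every problem in the document is reported (not just
# the first), so an author fixes a recipe in one pass. An empty diagnostic
# list is the precondition for compilation — any unknown name anywhere
# prevents execution (fail closed, no partial templates).

diagnostic <- function(kind, message, where = "") {
  list(kind = kind, message = message, where = where)
}

#' Validate a recipe document
#'
#' Collects all semantic problems: unresolvable symbol names (with a
#' nearest-name suggestion), arity mismatches, literal arguments that do
#' not coerce to their declared type, alias cycles, rules scoped to level
#' k < 1, rules with counteractions but no conditions, duplicate or
#' unknown aggregator references, and mapper/reducer type mismatches.
#'
#' @param doc an `rfs_recipe` from [parse_recipe()].
#' @param registry symbol registry, default [default_registry()].
#' @return list of diagnostics (each with `$kind`, `$message`, `$where`);
#'   empty if and only if the document is compilable.
#' @export
validate_document <- function(doc, registry = default_registry()) {
  stopifnot(inherits(doc, "rfs_recipe"))
  diags <- list()
  add <- function(d) diags[[length(diags) + 1L]] <<- d

  defs <- doc$global$shared_definitions
  # alias cycles
  for (nm in names(defs)) {
    cyc <- alias_cycle(nm, defs)
    if (!is.null(cyc)) {
      add(diagnostic("alias_cycle",
                     paste0("shared definition '", nm,
                            "' participates in a cycle: ",
                            paste(cyc, collapse = " -> ")),
                     paste0("shared_definitions.", nm)))
    }
  }
  acyclic <- length(diags) == 0L

  check_sym <- function(s, role, where) {
    if (acyclic) {
      s <- tryCatch(expand_alias(s, defs),
                    error = function(e) s)
    }
    for (d in symbol_diagnostics(s, role, registry, where, defs,
                                 doc$global$aggregators)) add(d)
  }

  for (rule in doc$rules) {
    where <- paste0("template.", rule$scope)
    if (!is.na(rule$level) && rule$level < 1L) {
      add(diagnostic("bad_level",
                     paste0(where, ": level must be >= 1 ",
                            "(the input root's children are depth 1)"),
                     where))
    }
    if (length(rule$conditions) == 0L) {
      add(diagnostic(
        "missing_conditions",
        paste0(where, ": a rule needs at least one condition",
               if (length(rule$counteractions) > 0L)
                 " (counteractions without conditions can never fire)"
               else ""),
        where))
    }
    for (s in rule$conditions) check_sym(s, "condition", where)
    for (s in rule$actions) check_sym(s, "action", where)
    for (s in rule$counteractions) check_sym(s, "action", where)
  }

  aggs <- doc$global$aggregators
  nms <- vapply(aggs, `[[`, "", "name")
  for (nm in unique(nms[duplicated(nms)])) {
    add(diagnostic("duplicate_aggregator",
                   paste0("aggregator name '", nm, "' is declared twice"),
                   "global.aggregators"))
  }
  for (a in aggs) {
    where <- paste0("aggregator '", a$name, "'")
    red <- reducer_table()[[a$reducer]]
    if (is.null(red)) {
      add(diagnostic("unknown_reducer",
                     paste0(where, ": unknown reducer '", a$reducer, "'",
                            suggest(a$reducer, names(reducer_table()))),
                     where))
    }
    check_sym(a$filter, "condition", where)
    mapper <- a$mapper %||% new_symbol(default_mapper_for(a$reducer))
    check_sym(mapper, "mapper", where)
    if (!is.null(red)) {
      ment <- registry_lookup(registry, "mapper", mapper$name)
      mtype <- mapper_output_type(mapper$name)
      if (!is.null(ment) && !is.null(red$element_type) &&
          !identical(red$element_type, "any") &&
          !identical(mtype, red$element_type)) {
        add(diagnostic("type_mismatch",
                       paste0(where, ": reducer '", a$reducer, "' consumes ",
                              red$element_type, " elements but mapper '",
                              mapper$name, "' produces ", mtype), where))
      }
    }
    if (!is.null(a$sort_key)) {
      ok <- tryCatch({grepl(a$sort_key, "probe", perl = TRUE); TRUE},
                     error = function(e) FALSE)
      if (!ok) add(diagnostic("bad_pattern",
                              paste0(where, ": sort_key is not a valid ",
                                     "regular expression"), where))
    }
  }
  diags
}

alias_cycle <- function(start, defs) {
  seen <- character(0)
  nm <- start
  while (nm %in% names(defs)) {
    if (nm %in% seen) return(c(seen, nm))
    seen <- c(seen, nm)
    nxt <- defs[[nm]]
    nm <- nxt$name
  }
  NULL
}

# Substitute aliases (zero-argument references to shared_definitions) until
# none remain, so the execution engine never sees an alias. Negation on the
# reference is xor-ed with the definition's.
expand_alias <- function(s, defs, depth = 0L) {
  if (depth > 100L) stop("alias expansion too deep", call. = FALSE)
  if (s$name %in% names(defs)) {
    if (length(s$args) > 0L) {
      stop("alias '", s$name, "' used with arguments", call. = FALSE)
    }
    def <- defs[[s$name]]
    out <- new_symbol(def$name, def$args, xor(def$negated, s$negated))
    return(expand_alias(out, defs, depth + 1L))
  }
  s$args <- lapply(s$args, function(a)
    if (is_symbol(a)) expand_alias(a, defs, depth + 1L) else a)
  s
}

symbol_diagnostics <- function(s, role, registry, where, defs, aggregators) {
  out <- list()
  if (s$name %in% names(defs)) {
    if (length(s$args) > 0L) {
      return(list(diagnostic("alias_with_args",
                             paste0(where, ": alias '", s$name,
                                    "' cannot take arguments"), where)))
    }
    return(out)  # expanded upstream when acyclic
  }
  entry <- registry_lookup(registry, role, s$name)
  if (is.null(entry)) {
    pool <- c(registry_names(registry, role), names(defs))
    return(list(diagnostic("unknown_symbol",
                           paste0(where, ": unknown ", role, " '", s$name,
                                  "'", suggest(s$name, pool)), where)))
  }
  n <- length(s$args)
  if (n < entry$sig$min || n > entry$sig$max) {
    out <- c(out, list(diagnostic(
      "arity_mismatch",
      paste0(where, ": '", s$name, "' takes ",
             format_arity(entry$sig), ", got ", n), where)))
    return(out)
  }
  type <- entry$sig$type
  for (i in seq_along(s$args)) {
    a <- s$args[[i]]
    if (identical(type, "symbol")) {
      sub <- if (is_symbol(a)) a else split_not(a, where)
      out <- c(out, symbol_diagnostics(sub, role, registry, where, defs,
                                       aggregators))
    } else if (identical(type, "transform")) {
      sub <- if (is_symbol(a)) a else split_not(a, where)
      out <- c(out, symbol_diagnostics(sub, "transform", registry, where,
                                       defs, aggregators))
    } else {
      if (is_symbol(a)) {
        out <- c(out, list(diagnostic(
          "bad_argument",
          paste0(where, ": argument ", i, " of '", s$name,
                 "' must be a literal, not a call"), where)))
      } else if (!coercible(a, type)) {
        out <- c(out, list(diagnostic(
          "bad_argument",
          paste0(where, ": argument ", i, " of '", s$name, "' ('", a,
                 "') is not a valid ", type), where)))
      }
    }
  }
  if (!s$negated && role == "action" &&
      s$name %in% c("add_to_aggregator")) {
    nms <- vapply(aggregators, `[[`, "", "name")
    if (length(s$args) == 1L && !is_symbol(s$args[[1L]]) &&
        !(s$args[[1L]] %in% nms)) {
      out <- c(out, list(diagnostic(
        "unknown_aggregator",
        paste0(where, ": add_to_aggregator names '", s$args[[1L]],
               "', which is not a declared aggregator"), where)))
    }
  }
  if (s$negated && role %in% c("action", "mapper", "transform")) {
    out <- c(out, list(diagnostic(
      "bad_negation",
      paste0(where, ": '", s$name, "' is an ", role,
             "; only conditions can be negated"), where)))
  }
  out
}

format_arity <- function(sg) {
  if (sg$min == sg$max) {
    paste0(sg$min, " argument", if (sg$min == 1L) "" else "s")
  } else if (is.infinite(sg$max)) {
    paste0("at least ", sg$min, " argument", if (sg$min == 1L) "" else "s")
  } else {
    paste0(sg$min, " to ", sg$max, " arguments")
  }
}

coercible <- function(x, type) {
  if (is.null(type) || type == "string") return(is_scalar_string(x))
  if (type == "int") return(grepl("^-?[0-9]+$", x))
  if (type == "number") {
    return(!is.na(suppressWarnings(as.numeric(x))))
  }
  TRUE
}

coerce_literal <- function(x, type) {
  if (is.null(type) || type == "string") return(x)
  if (type == "int") return(as.integer(x))
  if (type == "number") return(as.numeric(x))
  x
}

suggest <- function(name, pool) {
  if (length(pool) == 0L) return("")
  d <- utils::adist(name, pool, ignore.case = TRUE)
  best <- pool[which.min(d)]
  if (min(d) <= max(2L, nchar(name) %/% 2L)) {
    paste0("; did you mean '", best, "'?")
  } else ""
}
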