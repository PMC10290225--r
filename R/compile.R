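# Compilation turns a validated document into closures: every symbol
# reference becomes a callable with its literal arguments bound, aliases
# are substituted away, and condition lists become short-circuit
# conjunctions/disjunctions in author order. Compilation is pure — it
# never touches the filesystem; all path work happens at execution.

#' Compile a recipe document into an executable template
#'
#' Fails closed: if [validate_document()] reports any diagnostic the
#' template is refused — no partial templates exist. With
#' `act_on_success = false` in the recipe, the action and counteraction
#' sequences are swapped at compile time, so actions fire on nodes that
#' fail their conditions.
#'
#' @param doc an `rfs_recipe`.
#' @param registry symbol registry, default [default_registry()].
#' @return an object of class `rfs_template` for [execute_template()].
#' @export
compile_template <- function(doc, registry = default_registry()) {
  stopifnot(inherits(doc, "rfs_recipe"))
  diags <- validate_document(doc, registry)
  if (length(diags) > 0L) {
    stop("recipe does not validate (", length(diags), " problem",
         if (length(diags) > 1L) "s" else "", "):\n",
         paste(vapply(diags, `[[`, "", "message"), collapse = "\n"),
         call. = FALSE)
  }
  defs <- doc$global$shared_definitions

  by_level <- list()
  fallback <- NULL
  for (rule in doc$rules) {
    compiled <- compile_rule(rule, doc$global, defs, registry)
    if (rule$scope == "any") {
      fallback <- compiled
    } else {
      by_level[[as.character(rule$level)]] <- compiled
    }
  }

  aggregators <- lapply(doc$global$aggregators, function(a) {
    mapper <- a$mapper %||% new_symbol(default_mapper_for(a$reducer))
    list(
      name = a$name,
      filter = compile_condition(a$filter, defs, registry),
      mapper = compile_mapper(mapper, defs, registry),
      reducer_name = a$reducer,
      reducer = reducer_table()[[a$reducer]],
      sort_key = a$sort_key,
      threshold_a = a$threshold_a,
      threshold_b = a$threshold_b,
      sink = a$sink
    )
  })
  names(aggregators) <- vapply(aggregators, `[[`, "", "name")

  structure(
    list(by_level = by_level, fallback = fallback,
         aggregators = aggregators, config = doc$global,
         base_dir = doc$base_dir,
         has_quit = recipe_has_quit(doc)),
    class = "rfs_template")
}

#' @export
print.rfs_template <- function(x, ...) {
  cat("<rfs_template> levels:",
      paste(names(x$by_level), collapse = ","),
      "| any rule:", !is.null(x$fallback),
      "| aggregators:", paste(names(x$aggregators), collapse = ","), "\n")
  invisible(x)
}

compile_rule <- function(rule, global, defs, registry) {
  preds <- lapply(rule$conditions, compile_condition, defs = defs,
                  registry = registry)
  predicate <- if (rule$condition_mode == "all") {
    function(node, ctx) {
      for (p in preds) if (!p(node, ctx)) return(FALSE)
      TRUE
    }
  } else {
    function(node, ctx) {
      for (p in preds) if (p(node, ctx)) return(TRUE)
      FALSE
    }
  }
  on_success <- lapply(rule$actions, compile_action, defs = defs,
                       registry = registry)
  on_failure <- lapply(rule$counteractions, compile_action, defs = defs,
                       registry = registry)
  if (!global$act_on_success) {
    tmp <- on_success
    on_success <- on_failure
    on_failure <- tmp
  }
  list(scope = rule$scope, predicate = predicate,
       on_success = on_success, on_failure = on_failure,
       counts_failures = length(rule$counteractions) == 0L)
}

# condition -> function(node, ctx) -> flag; errors inside a predicate
# (e.g. a node vanished mid-run) journal a warning and evaluate FALSE so a
# single bad node cannot kill a long run.
compile_condition <- function(s, defs, registry) {
  s <- expand_alias(s, defs)
  fn <- if (s$name == "all_of") {
    subs <- lapply(s$args, function(a)
      compile_condition(as_sub_symbol(a), defs, registry))
    function(node, ctx) {
      for (p in subs) if (!p(node, ctx)) return(FALSE)
      TRUE
    }
  } else if (s$name == "any_of") {
    subs <- lapply(s$args, function(a)
      compile_condition(as_sub_symbol(a), defs, registry))
    function(node, ctx) {
      for (p in subs) if (p(node, ctx)) return(TRUE)
      FALSE
    }
  } else if (s$name == "not") {
    sub <- compile_condition(as_sub_symbol(s$args[[1L]]), defs, registry)
    function(node, ctx) !sub(node, ctx)
  } else {
    entry <- registry_lookup(registry, "condition", s$name)
    if (is.null(entry) || is.null(entry$fn)) {
      stop("unresolved condition '", s$name, "' survived validation",
           call. = FALSE)
    }
    raw <- entry$fn(lapply(s$args, coerce_literal, type = entry$sig$type))
    nm <- s$name
    function(node, ctx) {
      tryCatch(isTRUE(raw(node, ctx)), error = function(e) {
        journal_add(ctx, "warn", node$rel,
                    paste0("condition '", nm, "' errored: ",
                           conditionMessage(e)))
        FALSE
      })
    }
  }
  if (s$negated) {
    pos <- fn
    fn <- function(node, ctx) !pos(node, ctx)
  }
  fn
}

as_sub_symbol <- function(a) if (is_symbol(a)) a else split_not(a, "composite")

compile_action <- function(s, defs, registry) {
  s <- expand_alias(s, defs)
  entry <- registry_lookup(registry, "action", s$name)
  if (is.null(entry)) {
    stop("unresolved action '", s$name, "' survived validation", call. = FALSE)
  }
  args <- if (identical(entry$sig$type, "transform")) {
    lapply(s$args, function(a)
      compile_transform(as_sub_symbol(a), defs, registry))
  } else {
    lapply(s$args, coerce_literal, type = entry$sig$type)
  }
  entry$fn(args)
}

compile_transform <- function(s, defs, registry) {
  s <- expand_alias(s, defs)
  entry <- registry_lookup(registry, "transform", s$name)
  if (is.null(entry)) {
    stop("unresolved transform '", s$name, "'", call. = FALSE)
  }
  entry$fn(lapply(s$args, coerce_literal, type = entry$sig$type))
}

compile_mapper <- function(s, defs, registry) {
  s <- expand_alias(s, defs)
  entry <- registry_lookup(registry, "mapper", s$name)
  if (is.null(entry)) {
    stop("unresolved mapper '", s$name, "'", call. = FALSE)
  }
  entry$fn(lapply(s$args, coerce_literal, type = entry$sig$type))
}

recipe_has_quit <- function(doc) {
  defs <- doc$global$shared_definitions
  hit <- function(s) {
    s <- tryCatch(expand_alias(s, defs), error = function(e) s)
    if (s$name %in% c("quit", "quit_on_fail")) return(TRUE)
    any(vapply(s$args, function(a) is_symbol(a) && hit(a), TRUE))
  }
  for (rule in doc$rules) {
    for (s in c(rule$actions, rule$counteractions)) if (hit(s)) return(TRUE)
  }
  FALSE
}
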