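# The recipe dialect
# ------------------
# A recipe is TOML with two top-level tables:
#
#   [global]                       required
#     input_root = "data"          required; relative to the recipe file
#     traversal_order = "topdown"  topdown | bottomup
#     parallel = false
#     act_on_success = true        false: actions fire on FAILING nodes
#     regex_enabled = false        name patterns as perl regex vs substring
#     destructive_allowed = false  remove() really deletes (with CLI opt-in)
#     quarantine_dir = "..."       optional; default "<input_root>.quarantine"
#   [global.shared_definitions]    reusable aliases, name = <symbol>
#   [[global.aggregators]]         filter-map-reduce pipelines
#     name / filter / mapper / reducer / sort_key /
#     threshold_a / threshold_b / sink = { kind, destination }
#   [template.any]                 rule for nodes at any depth
#   [template.level_2]             rule for nodes at depth 2 (root children
#     conditions = [...]           are depth 1); a level rule beats "any"
#     condition_mode = "all"       all | any, left-to-right short circuit
#     actions = [...]
#     counteractions = [...]
#
# A symbol is written as a bare string ("is_file", "not is_hidden") or an
# array whose head is the name and whose tail are arguments; ALL literal
# arguments are written as TOML strings and coerced to their declared type
# (["size_at_least", "1024"]). Composite conditions nest:
# ["any_of", "is_dir", ["all_of", "is_file", ["has_extension", ".tif"]]].
# Unknown keys anywhere are hard errors: a recipe is a contract, and a
# silently ignored typo would void it.

GLOBAL_KEYS <- c("input_root", "traversal_order", "parallel",
                 "act_on_success", "regex_enabled", "destructive_allowed",
                 "quarantine_dir", "shared_definitions", "aggregators")
AGG_KEYS <- c("name", "filter", "mapper", "reducer", "sort_key",
              "threshold_a", "threshold_b", "sink")
SINK_KEYS <- c("kind", "destination")
RULE_KEYS <- c("conditions", "condition_mode", "actions", "counteractions")
SINK_KINDS <- c("stdout", "text_list", "csv_table", "image_file")

#' Parse a TOML recipe into a recipe document
#'
#' Applies defaults (`traversal_order = "topdown"`, `parallel = false`,
#' `act_on_success = true`, `regex_enabled = false`,
#' `destructive_allowed = false`) and rejects — as hard errors — TOML syntax
#' problems, unrecognized keys (naming the key and its line), a missing
#' `input_root`, duplicated rule scopes, and recipes that declare neither a
#' rule nor an aggregator.
#'
#' @param toml_text recipe source as a single string or character vector of
#'   lines.
#' @param base_dir directory against which relative paths in the recipe are
#'   resolved (for [read_recipe()], the recipe file's directory).
#' @return an object of class `rfs_recipe`.
#' @seealso [read_recipe()], [validate_document()], [compile_template()]
#' @export
parse_recipe <- function(toml_text, base_dir = getwd()) {
  text <- paste(toml_text, collapse = "\n")
  raw <- tryCatch(
    RcppTOML::parseTOML(input = text, fromFile = FALSE, escape = FALSE),
    error = function(e) stop("TOML syntax error: ", conditionMessage(e),
                             call. = FALSE))
  check_keys(raw, c("global", "template"), "", text)
  if (is.null(raw$global)) recipe_error("missing [global] table", text, "global")
  check_keys(raw$global, GLOBAL_KEYS, "global", text)

  g <- raw$global
  if (!is_scalar_string(g$input_root) || !nzchar(g$input_root)) {
    recipe_error("missing or empty global.input_root", text, "input_root")
  }
  order <- g$traversal_order %||% "topdown"
  if (!order %in% c("topdown", "bottomup")) {
    recipe_error(paste0("traversal_order must be 'topdown' or 'bottomup', got '",
                        order, "'"), text, "traversal_order")
  }
  global <- list(
    input_root = g$input_root,
    traversal_order = order,
    parallel = isTRUE(g$parallel),
    act_on_success = !isFALSE(g$act_on_success),
    regex_enabled = isTRUE(g$regex_enabled),
    destructive_allowed = isTRUE(g$destructive_allowed),
    quarantine_dir = g$quarantine_dir,
    shared_definitions = parse_shared_definitions(g$shared_definitions, text),
    aggregators = parse_aggregators(g$aggregators, text)
  )

  rules <- parse_rules(raw$template, text)
  if (length(rules) == 0L && length(global$aggregators) == 0L) {
    stop("invalid recipe: at least one rule or aggregator required",
         call. = FALSE)
  }
  structure(
    list(global = global, rules = rules, base_dir = base_dir,
         source = text, source_locations = key_line_index(text)),
    class = "rfs_recipe")
}

#' Read and parse a recipe file
#'
#' @param path TOML recipe file; relative paths inside the recipe resolve
#'   against this file's directory.
#' @return an `rfs_recipe`, as [parse_recipe()].
#' @export
read_recipe <- function(path) {
  if (!file.exists(path)) stop("recipe file not found: ", path, call. = FALSE)
  parse_recipe(readLines(path, warn = FALSE, encoding = "UTF-8"),
               base_dir = dirname(normalizePath(path, winslash = "/")))
}

#' @export
print.rfs_recipe <- function(x, ...) {
  cat("<rfs_recipe> input_root:", x$global$input_root,
      "| rules:", length(x$rules),
      "| aggregators:", length(x$global$aggregators), "\n")
  invisible(x)
}

parse_shared_definitions <- function(defs, text) {
  if (is.null(defs)) return(list())
  if (!is.list(defs) || is.null(names(defs))) {
    recipe_error("shared_definitions must be a table of name = symbol",
                 text, "shared_definitions")
  }
  out <- list()
  for (nm in names(defs)) {
    out[[nm]] <- symbol_from_toml(defs[[nm]],
                                  paste0("shared_definitions.", nm))
  }
  out
}

parse_aggregators <- function(aggs, text) {
  if (is.null(aggs)) return(list())
  if (!is.list(aggs)) recipe_error("aggregators must be an array of tables",
                                   text, "aggregators")
  lapply(seq_along(aggs), function(i) {
    a <- aggs[[i]]
    where <- paste0("global.aggregators[", i, "]")
    if (!is.list(a)) recipe_error(paste0(where, " must be a table"),
                                  text, "aggregators")
    check_keys(a, AGG_KEYS, where, text)
    if (!is_scalar_string(a$name) || !nzchar(a$name)) {
      recipe_error(paste0(where, " needs a non-empty name"), text, "name")
    }
    if (!is_scalar_string(a$reducer)) {
      recipe_error(paste0(where, " ('", a$name %||% "?",
                          "') needs a reducer"), text, "reducer")
    }
    sink <- a$sink %||% list(kind = "stdout")
    check_keys(sink, SINK_KEYS, paste0(where, ".sink"), text)
    kind <- sink$kind %||% "stdout"
    if (!kind %in% SINK_KINDS) {
      recipe_error(paste0("unknown sink kind '", kind, "' in ", where,
                          " (one of: ", paste(SINK_KINDS, collapse = ", "),
                          ")"), text, "kind")
    }
    if (kind != "stdout" && !is_scalar_string(sink$destination)) {
      recipe_error(paste0("sink kind '", kind, "' in ", where,
                          " needs a destination"), text, "sink")
    }
    list(
      name = a$name,
      filter = if (is.null(a$filter)) new_symbol("is_file")
               else symbol_from_toml(a$filter, paste0(where, ".filter")),
      mapper = if (is.null(a$mapper)) NULL
               else symbol_from_toml(a$mapper, paste0(where, ".mapper")),
      reducer = a$reducer,
      sort_key = a$sort_key,
      threshold_a = as_number_or(a$threshold_a, 0, text, "threshold_a"),
      threshold_b = as_number_or(a$threshold_b, 0, text, "threshold_b"),
      sink = list(kind = kind, destination = sink$destination)
    )
  })
}

as_number_or <- function(x, default, text, key) {
  if (is.null(x)) return(default)
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) recipe_error(paste0(key, " must be numeric, got '", x, "'"),
                             text, key)
  v
}

parse_rules <- function(template, text) {
  if (is.null(template) || (is.list(template) && length(template) == 0L)) {
    return(list())
  }
  if (!is.list(template) || is.null(names(template))) {
    recipe_error("[template] must contain rule tables", text, "template")
  }
  rules <- list()
  for (scope_name in names(template)) {
    if (scope_name != "any" && !grepl("^level_[0-9]+$", scope_name)) {
      recipe_error(paste0("unknown rule scope [template.", scope_name,
                          "]; expected 'any' or 'level_<k>'"),
                   text, scope_name)
    }
    block <- template[[scope_name]]
    where <- paste0("template.", scope_name)
    check_keys(block, RULE_KEYS, where, text)
    mode <- block$condition_mode %||% "all"
    if (!mode %in% c("all", "any")) {
      recipe_error(paste0(where, ": condition_mode must be 'all' or 'any'"),
                   text, "condition_mode")
    }
    rules[[scope_name]] <- list(
      scope = scope_name,
      level = if (scope_name == "any") NA_integer_
              else as.integer(sub("^level_", "", scope_name)),
      conditions = parse_symbol_list(block$conditions,
                                     paste0(where, ".conditions")),
      condition_mode = mode,
      actions = parse_symbol_list(block$actions, paste0(where, ".actions")),
      counteractions = parse_symbol_list(block$counteractions,
                                         paste0(where, ".counteractions"))
    )
  }
  # deterministic rule order: any first, then ascending level
  ord <- order(vapply(names(rules), function(n) {
    if (n == "any") -1L else as.integer(sub("^level_", "", n))
  }, 0L))
  unname(rules[ord])
}

# The conditions/actions/counteractions arrays hold SYMBOLS: a bare string
# element is a zero-argument symbol; a call with arguments must be wrapped
# in its own array, e.g. conditions = [["has_extension", ".csv"], "is_file"].
parse_symbol_list <- function(x, where) {
  if (is.null(x)) return(list())
  if (is.character(x)) x <- as.list(x)  # all elements are bare names
  if (!is.list(x)) stop("recipe error at ", where,
                        ": expected an array of symbols", call. = FALSE)
  lapply(seq_along(x), function(i)
    symbol_from_toml(x[[i]], paste0(where, "[", i, "]")))
}

# ---- unknown-key contract -------------------------------------------------

check_keys <- function(table, allowed, where, text) {
  if (is.null(table)) return(invisible(NULL))
  if (!is.list(table)) return(invisible(NULL))
  bad <- setdiff(names(table), allowed)
  if (length(bad) > 0L) {
    lines <- vapply(bad, function(k) find_key_line(text, k), 0L)
    msg <- paste0("unknown key", if (length(bad) > 1L) "s" else "", " ",
                  paste0("'", if (nzchar(where)) paste0(where, ".") else "",
                         bad, "'",
                         ifelse(is.na(lines), "",
                                paste0(" (line ", lines, ")")),
                         collapse = ", "),
                  "; known keys here: ", paste(allowed, collapse = ", "))
    stop("invalid recipe: ", msg, call. = FALSE)
  }
  invisible(NULL)
}

# Best-effort source location of a key: first line defining or naming it.
find_key_line <- function(text, key) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  pat <- paste0("^\\s*(\"|')?", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", key),
                "(\"|')?\\s*=")
  hit <- grep(pat, lines)
  if (length(hit) == 0L) {
    hit <- grep(paste0("\\[.*", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", key),
                       ".*\\]"), lines)
  }
  if (length(hit) == 0L) NA_integer_ else hit[[1L]]
}

# Best-effort map from key / table-header name to source line, kept on the
# document for diagnostics.
key_line_index <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  keyed <- grepl("^\\s*[A-Za-z0-9_\"'.-]+\\s*=", lines)
  header <- grepl("^\\s*\\[", lines)
  nm <- character(length(lines))
  nm[keyed] <- sub("^\\s*([A-Za-z0-9_\"'.-]+)\\s*=.*$", "\\1", lines[keyed])
  nm[header] <- gsub("[][]", "", trimws(lines[header]))
  keep <- keyed | header
  stats::setNames(which(keep), nm[keep])
}

recipe_error <- function(msg, text, key) {
  line <- find_key_line(text, key)
  stop("invalid recipe: ", msg,
       if (!is.na(line)) paste0(" (line ", line, ")") else "",
       call. = FALSE)
}
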