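#' Canonical serialization of a recipe document
#'
#' Renders a parsed recipe back to TOML in a fixed key order with all
#' defaults written explicitly. Reparsing the output yields a document
#' equal to the original (the canonical round-trip used by the test
#' suite and handy for documenting an inherited recipe).
#'
#' @param doc an `rfs_recipe`.
#' @return single TOML string.
#' @export
serialize_recipe <- function(doc) {
  stopifnot(inherits(doc, "rfs_recipe"))
  g <- doc$global
  out <- c(
    "[global]",
    paste0("input_root = ", toml_str(g$input_root)),
    paste0("traversal_order = ", toml_str(g$traversal_order)),
    paste0("parallel = ", toml_bool(g$parallel)),
    paste0("act_on_success = ", toml_bool(g$act_on_success)),
    paste0("regex_enabled = ", toml_bool(g$regex_enabled)),
    paste0("destructive_allowed = ", toml_bool(g$destructive_allowed)),
    if (!is.null(g$quarantine_dir))
      paste0("quarantine_dir = ", toml_str(g$quarantine_dir))
  )
  if (length(g$shared_definitions) > 0L) {
    out <- c(out, "", "[global.shared_definitions]")
    for (nm in names(g$shared_definitions)) {
      out <- c(out, paste0(nm, " = ",
                           toml_value(symbol_to_toml(g$shared_definitions[[nm]]))))
    }
  }
  for (a in g$aggregators) {
    out <- c(out, "", "[[global.aggregators]]",
             paste0("name = ", toml_str(a$name)),
             paste0("filter = ", toml_value(symbol_to_toml(a$filter))),
             if (!is.null(a$mapper))
               paste0("mapper = ", toml_value(symbol_to_toml(a$mapper))),
             paste0("reducer = ", toml_str(a$reducer)),
             if (!is.null(a$sort_key))
               paste0("sort_key = ", toml_str(a$sort_key)),
             if (a$threshold_a != 0)
               paste0("threshold_a = ", toml_str(format(a$threshold_a))),
             if (a$threshold_b != 0)
               paste0("threshold_b = ", toml_str(format(a$threshold_b))),
             paste0("sink = { kind = ", toml_str(a$sink$kind),
                    if (!is.null(a$sink$destination))
                      paste0(", destination = ", toml_str(a$sink$destination)),
                    " }"))
  }
  for (rule in doc$rules) {
    out <- c(out, "", paste0("[template.", rule$scope, "]"),
             paste0("conditions = ", toml_symbol_list(rule$conditions)),
             paste0("condition_mode = ", toml_str(rule$condition_mode)),
             if (length(rule$actions) > 0L)
               paste0("actions = ", toml_symbol_list(rule$actions)),
             if (length(rule$counteractions) > 0L)
               paste0("counteractions = ",
                      toml_symbol_list(rule$counteractions)))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

toml_str <- function(x) {
  paste0('"', gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", x)), '"')
}

toml_bool <- function(x) if (isTRUE(x)) "true" else "false"

toml_value <- function(x) {
  if (is.list(x)) {
    paste0("[", paste(vapply(x, toml_value, ""), collapse = ", "), "]")
  } else {
    toml_str(x)
  }
}

toml_symbol_list <- function(symbols) {
  vals <- vapply(symbols, function(s) {
    v <- symbol_to_toml(s)
    if (is.list(v)) toml_value(v) else toml_str(v)
  }, "")
  paste0("[", paste(vals, collapse = ", "), "]")
}
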