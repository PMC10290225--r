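# Symbol expressions: the parsed form of a named condition/action/mapper
# reference in a recipe, e.g. ["has_extension", ".csv"] or "not is_file".
# Arguments are either literal strings (coerced to their declared type at
# validation) or nested symbol expressions (for composites and transforms).

new_symbol <- function(name, args = list(), negated = FALSE) {
  stopifnot(is_scalar_string(name), nzchar(name), is.list(args), is_flag(negated))
  structure(list(name = name, args = args, negated = negated),
            class = "rfs_symbol")
}

is_symbol <- function(x) inherits(x, "rfs_symbol")

#' @export
print.rfs_symbol <- function(x, ...) {
  cat(format_symbol(x), "\n")
  invisible(x)
}

format_symbol <- function(s) {
  nm <- paste0(if (s$negated) "not " else "", s$name)
  if (length(s$args) == 0L) return(nm)
  args <- vapply(s$args, function(a)
    if (is_symbol(a)) format_symbol(a) else paste0('"', a, '"'), "")
  paste0(nm, "(", paste(args, collapse = ", "), ")")
}

# Parse a TOML value (string or possibly-nested list of strings) into a
# symbol expression. A bare string is a zero-argument call; an array is a
# call whose head is the name and whose tail are literal strings or nested
# calls. The prefix token "not " negates. (The TOML reader simplifies a
# homogeneous string array to an R character vector and a singleton array
# to a scalar; both shapes are accepted here.)
symbol_from_toml <- function(x, where = "symbol") {
  if (is_scalar_string(x)) {
    return(split_not(x, where))
  }
  if (is.character(x) && length(x) >= 2L) x <- as.list(x)
  if (is.list(x) && length(x) >= 1L) {
    head <- x[[1L]]
    if (!is_scalar_string(head)) {
      stop("recipe error at ", where,
           ": a call must start with a name string", call. = FALSE)
    }
    s <- split_not(head, where)
    s$args <- lapply(x[-1L], function(a) {
      if (is_scalar_string(a)) a
      else if (is.list(a) || (is.character(a) && length(a) >= 2L)) {
        symbol_from_toml(a, where)
      } else {
        stop("recipe error at ", where,
             ": arguments must be strings or nested calls", call. = FALSE)
      }
    })
    return(s)
  }
  stop("recipe error at ", where,
       ": expected a name string or a [name, args...] array", call. = FALSE)
}

split_not <- function(name, where) {
  negated <- FALSE
  nm <- trimws(name)
  if (grepl("^not\\s+", nm)) {
    negated <- TRUE
    nm <- sub("^not\\s+", "", nm)
  }
  if (!nzchar(nm)) {
    stop("recipe error at ", where, ": empty symbol name", call. = FALSE)
  }
  new_symbol(nm, negated = negated)
}

# Serialize back to the TOML value form (inverse of symbol_from_toml).
symbol_to_toml <- function(s) {
  nm <- paste0(if (s$negated) "not " else "", s$name)
  if (length(s$args) == 0L) return(nm)
  c(list(nm), lapply(s$args, function(a)
    if (is_symbol(a)) symbol_to_toml(a) else a))
}

# All names referenced by a symbol tree, with the roles they occupy.
symbol_names <- function(s) {
  out <- s$name
  for (a in s$args) if (is_symbol(a)) out <- c(out, symbol_names(a))
  out
}

#' Build a composite condition from existing ones
#'
#' Combines symbol expressions with a logical operator. Composites resolve
#' like any built-in condition and nest arbitrarily, so
#' `all_of(is_file, any_of(...))` expresses any boolean circuit over the
#' predicate vocabulary.
#'
#' @param op one of `"all_of"`, `"any_of"`, `"not"` (`not` takes exactly
#'   one expression).
#' @param exprs list of symbol expressions (from [compose()] itself, or
#'   names given as strings).
#' @return a symbol expression usable in [compile_template()] pipelines.
#' @examples
#' compose("all_of", list("is_file", compose("not", list("is_hidden"))))
#' @export
compose <- function(op, exprs) {
  op <- match.arg(op, c("all_of", "any_of", "not"))
  if (!is.list(exprs)) exprs <- list(exprs)
  if (length(exprs) == 0L) stop("compose: exprs must be non-empty", call. = FALSE)
  if (op == "not" && length(exprs) != 1L) {
    stop("compose: 'not' takes exactly one expression", call. = FALSE)
  }
  args <- lapply(exprs, function(e) {
    if (is_symbol(e)) e
    else if (is_scalar_string(e)) split_not(e, "compose")
    else stop("compose: expressions must be symbols or names", call. = FALSE)
  })
  new_symbol(op, args = args)
}
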