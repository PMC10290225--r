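# The registry maps symbol names to implementations plus declared
# signatures, per role: conditions (Node -> flag, never mutate the tree),
# actions (side effects, journaled), mappers (Node -> aggregation
# contribution) and rename transforms. Lookup is role-aware: the same name
# may exist in several roles; a rule position decides which map is used.

# A signature declares argument count bounds and the (homogeneous) argument
# type: "string", "int", "number", "symbol" (nested call), "transform".
sig <- function(min = 0L, max = min, type = NULL) {
  list(min = as.integer(min),
       max = if (is.infinite(max)) Inf else as.integer(max),
       type = type)
}

#' Create the default symbol registry
#'
#' Returns a registry holding every built-in condition, action, mapper and
#' rename transform, ready for [compile_template()]. Extend it with
#' [register_user_symbol()].
#'
#' @return an object of class `rfs_registry`.
#' @seealso [builtin_conditions()], [builtin_actions()]
#' @export
default_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$conditions <- builtin_condition_table()
  reg$actions <- builtin_action_table()
  reg$mappers <- builtin_mapper_table()
  reg$transforms <- builtin_transform_table()
  class(reg) <- "rfs_registry"
  reg
}

#' @export
print.rfs_registry <- function(x, ...) {
  cat("<rfs_registry>\n")
  for (role in c("conditions", "actions", "mappers", "transforms")) {
    cat(" ", role, ": ", paste(byte_sort(names(x[[role]])), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

registry_lookup <- function(registry, role, name) {
  tab <- registry[[paste0(role, "s")]]
  if (is.null(tab)) return(NULL)
  tab[[name]]
}

registry_names <- function(registry, role) names(registry[[paste0(role, "s")]])

#' List the built-in condition names
#'
#' Conditions are total predicates over filesystem nodes: a condition
#' applied to a path that vanished mid-run evaluates to `FALSE` and
#' journals a warning rather than failing the run. Conditions never mutate
#' the filesystem.
#'
#' @return sorted character vector of names.
#' @export
builtin_conditions <- function() byte_sort(names(builtin_condition_table()))

#' List the built-in action names
#'
#' Mutating actions journal exactly one effect each, honour dry-run mode
#' (effect journaled, mutation skipped), and never overwrite silently:
#' destination collisions get a `_1`, `_2`, ... suffix before the
#' extension. `remove` quarantines by default; true deletion needs
#' `destructive_allowed` in the recipe AND the run option.
#'
#' @return sorted character vector of names.
#' @export
builtin_actions <- function() byte_sort(names(builtin_action_table()))

builtin_mappers <- function() byte_sort(names(builtin_mapper_table()))
builtin_transforms <- function() byte_sort(names(builtin_transform_table()))

# ---- conditions -----------------------------------------------------------

# Each entry: fn = factory(coerced_args) -> function(node, ctx) -> flag.
# Factories close over their literal arguments (currying at compile time).
builtin_condition_table <- function() {
  list(
    always = list(fn = function(args) function(node, ctx) TRUE, sig = sig()),
    never = list(fn = function(args) function(node, ctx) FALSE, sig = sig()),
    is_file = list(fn = function(args) function(node, ctx) {
      file.exists(node$path) && !dir.exists(node$path)
    }, sig = sig()),
    is_dir = list(fn = function(args) function(node, ctx) {
      dir.exists(node$path)
    }, sig = sig()),
    is_hidden = list(fn = function(args) function(node, ctx) {
      startsWith(basename(node$path), ".")
    }, sig = sig()),
    has_extension = list(fn = function(args) {
      ext <- tolower(args[[1L]])
      if (!startsWith(ext, ".")) ext <- paste0(".", ext)
      function(node, ctx) file_ext_lower(node$path) == ext
    }, sig = sig(1L, 1L, "string")),
    name_matches = list(fn = function(args) {
      pat <- args[[1L]]
      function(node, ctx) {
        if (isTRUE(ctx$config$regex_enabled)) {
          grepl(pat, basename(node$path), perl = TRUE)
        } else {
          grepl(pat, basename(node$path), fixed = TRUE)
        }
      }
    }, sig = sig(1L, 1L, "string")),
    name_is_integer = list(fn = function(args) function(node, ctx) {
      grepl("^[0-9]+$", strip_ext(basename(node$path)))
    }, sig = sig()),
    size_at_least = list(fn = function(args) {
      n <- args[[1L]]
      function(node, ctx) {
        node$kind == "file" && isTRUE(file.size(node$path) >= n)
      }
    }, sig = sig(1L, 1L, "int")),
    size_at_most = list(fn = function(args) {
      n <- args[[1L]]
      function(node, ctx) {
        node$kind == "file" && isTRUE(file.size(node$path) <= n)
      }
    }, sig = sig(1L, 1L, "int")),
    is_image = list(fn = function(args) function(node, ctx) {
      node$kind == "file" && is_image_path(node$path)
    }, sig = sig()),
    image_has_dims = list(fn = function(args) {
      n <- args[[1L]]
      function(node, ctx) {
        if (node$kind != "file" || !is_image_path(node$path)) return(FALSE)
        image_ndims(read_image(node$path)) == n
      }
    }, sig = sig(1L, 1L, "int")),
    is_csv = list(fn = function(args) function(node, ctx) {
      node$kind == "file" && file_ext_lower(node$path) == ".csv"
    }, sig = sig()),
    csv_has_columns = list(fn = function(args) {
      cols <- unlist(args)
      function(node, ctx) {
        if (node$kind != "file" || file_ext_lower(node$path) != ".csv") {
          return(FALSE)
        }
        header <- names(utils::read.csv(node$path, nrows = 1L,
                                        check.names = FALSE))
        all(cols %in% header)
      }
    }, sig = sig(1L, Inf, "string")),
    path_depth_is = list(fn = function(args) {
      k <- args[[1L]]
      function(node, ctx) node$depth == k
    }, sig = sig(1L, 1L, "int")),
    # composites: compiled structurally by compile_template(); the entries
    # here carry the signatures so validation can check them uniformly
    all_of = list(fn = NULL, sig = sig(1L, Inf, "symbol")),
    any_of = list(fn = NULL, sig = sig(1L, Inf, "symbol")),
    not = list(fn = NULL, sig = sig(1L, 1L, "symbol"))
  )
}

# ---- actions --------------------------------------------------------------

# Factories -> function(node, ctx) -> NULL or "quit". Mutations go through
# mutate() so dry-run and journaling stay consistent.
builtin_action_table <- function() {
  list(
    warn = list(fn = function(args) {
      msg <- if (length(args) >= 1L) args[[1L]] else "rule warning"
      function(node, ctx) journal_add(ctx, "warn", node$rel, msg)
    }, sig = sig(0L, 1L, "string")),
    show = list(fn = function(args) function(node, ctx) {
      if (!isTRUE(ctx$quiet)) cat(node$rel, "\n", sep = "")
      journal_add(ctx, "log", node$rel, "show")
    }, sig = sig()),
    log_to_file = list(fn = function(args) {
      dest <- args[[1L]]
      function(node, ctx) {
        journal_add(ctx, "log", node$rel, paste0("log_to_file:", dest))
        if (!isTRUE(ctx$dry_run)) {
          full <- resolve_path(dest, ctx$base_dir)
          dir.create(dirname(full), recursive = TRUE, showWarnings = FALSE)
          cat(node$rel, "\n", file = full, sep = "", append = TRUE)
        }
      }
    }, sig = sig(1L, 1L, "string")),
    copy_to = list(fn = function(args) {
      destdir <- args[[1L]]
      function(node, ctx) {
        dest <- file.path(resolve_path(destdir, ctx$base_dir),
                          basename(node$path))
        do_copy(ctx, node, dest, "copy")
      }
    }, sig = sig(1L, 1L, "string")),
    move_to = list(fn = function(args) {
      destdir <- args[[1L]]
      function(node, ctx) {
        dest <- file.path(resolve_path(destdir, ctx$base_dir),
                          basename(node$path))
        do_move(ctx, node, dest, "move")
      }
    }, sig = sig(1L, 1L, "string")),
    flatten_to = list(fn = function(args) {
      destdir <- args[[1L]]
      function(node, ctx) {
        # path-derived unique name: relative path with separators -> "_"
        flat <- gsub("/", "_", node$rel, fixed = TRUE)
        dest <- file.path(resolve_path(destdir, ctx$base_dir), flat)
        do_copy(ctx, node, dest, "copy")
      }
    }, sig = sig(1L, 1L, "string")),
    remove = list(fn = function(args) function(node, ctx) {
      destructive <- isTRUE(ctx$config$destructive_allowed) &&
        isTRUE(ctx$allow_destructive)
      if (destructive) {
        journal_add(ctx, "delete", node$rel, "destructive remove")
        if (!isTRUE(ctx$dry_run)) {
          unlink(node$path, recursive = TRUE, force = TRUE)
        }
      } else {
        dest <- file.path(ctx$quarantine_dir, node$rel)
        journal_add(ctx, "quarantine", node$rel, rel_or_abs(dest, ctx))
        if (!isTRUE(ctx$dry_run)) {
          dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
          move_path(node$path, dest)
        }
      }
    }, sig = sig()),
    rename = list(fn = function(args) {
      # args are compiled transform closures applied left to right
      function(node, ctx) {
        name <- basename(node$path)
        for (tr in args) name <- tr(name)
        if (identical(name, basename(node$path))) return(invisible(NULL))
        dest <- file.path(dirname(node$path), name)
        do_move(ctx, node, dest, "rename")
      }
    }, sig = sig(1L, Inf, "transform")),
    add_to_list = list(fn = function(args) {
      nm <- args[[1L]]
      function(node, ctx) {
        ctx$lists[[nm]] <- c(ctx$lists[[nm]], node$rel)
        journal_add(ctx, "list_add", node$rel, nm)
      }
    }, sig = sig(1L, 1L, "string")),
    add_to_aggregator = list(fn = function(args) {
      nm <- args[[1L]]
      function(node, ctx) {
        journal_add(ctx, "aggregate_add", node$rel, nm)
        aggregator_offer(ctx, nm, node, force = TRUE)
      }
    }, sig = sig(1L, 1L, "string")),
    quit = list(fn = function(args) function(node, ctx) {
      journal_add(ctx, "quit", node$rel, "quit")
      "quit"
    }, sig = sig()),
    quit_on_fail = list(fn = function(args) function(node, ctx) {
      # a no-op on the success path; quits when the rule failed
      if (isFALSE(ctx$current_passed)) {
        journal_add(ctx, "quit", node$rel, "quit_on_fail")
        if (!is.null(ctx$shared)) ctx$shared$aborted <- TRUE
        return("quit")
      }
      invisible(NULL)
    }, sig = sig())
  )
}

resolve_path <- function(path, base_dir) {
  if (grepl("^(/|[A-Za-z]:)", path)) path else path_join(base_dir, path)
}

# journal-friendly destination: relative to the input root when inside it,
# else relative to the workspace (the root's parent), else absolute
rel_or_abs <- function(path, ctx) {
  rp <- rel_path(path, ctx$root)
  if (!startsWith(rp, "/")) return(rp)
  rp <- rel_path(path, dirname(ctx$root))
  if (!startsWith(rp, "/")) return(paste0("../", rp))
  path
}

do_copy <- function(ctx, node, dest, kind) {
  dest <- uncollide(dest)
  journal_add(ctx, kind, node$rel, rel_or_abs(dest, ctx))
  if (!isTRUE(ctx$dry_run)) {
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    ok <- if (node$kind == "directory") {
      dir.create(dest, showWarnings = FALSE)
      all(file.copy(list.files(node$path, full.names = TRUE, all.files = TRUE,
                               no.. = TRUE),
                    dest, recursive = TRUE))
    } else {
      file.copy(node$path, dest, overwrite = FALSE)
    }
    if (!isTRUE(ok)) {
      stop("action '", kind, "' failed for ", node$rel, " -> ", dest,
           call. = FALSE)
    }
  }
  invisible(NULL)
}

do_move <- function(ctx, node, dest, kind) {
  dest <- uncollide(dest)
  journal_add(ctx, kind, node$rel, rel_or_abs(dest, ctx))
  if (!isTRUE(ctx$dry_run)) {
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    move_path(node$path, dest)
  }
  invisible(NULL)
}

# rename with copy+delete fallback (cross-device safe)
move_path <- function(from, to) {
  if (suppressWarnings(file.rename(from, to))) return(invisible(TRUE))
  if (dir.exists(from)) {
    dir.create(to, showWarnings = FALSE, recursive = TRUE)
    ok <- all(file.copy(list.files(from, full.names = TRUE, all.files = TRUE,
                                   no.. = TRUE), to, recursive = TRUE))
  } else {
    ok <- file.copy(from, to, overwrite = FALSE)
  }
  if (!isTRUE(ok)) stop("cannot move ", from, " -> ", to, call. = FALSE)
  unlink(from, recursive = TRUE, force = TRUE)
  invisible(TRUE)
}

# ---- mappers --------------------------------------------------------------

# Mappers extract one contribution per accepted node for the aggregation
# engine. Image/table mappers attach the node's sort key so order-sensitive
# reducers can canonicalize at finalization.
builtin_mapper_table <- function() {
  list(
    node_path = list(fn = function(args) function(node, ctx) node$rel,
                     sig = sig()),
    node_name = list(fn = function(args) function(node, ctx)
      basename(node$path), sig = sig()),
    file_size = list(fn = function(args) function(node, ctx) {
      if (node$kind != "file") 0 else as.numeric(file.size(node$path))
    }, sig = sig()),
    load_image = list(fn = function(args) function(node, ctx) {
      list(key = node$sort_key, img = read_image(node$path), source = node$rel)
    }, sig = sig()),
    load_table = list(fn = function(args) function(node, ctx) {
      list(key = node$sort_key,
           df = utils::read.csv(node$path, check.names = FALSE),
           source = node$rel)
    }, sig = sig())
  )
}

# ---- rename transforms ----------------------------------------------------

builtin_transform_table <- function() {
  list(
    whitespace_to_underscore = list(
      fn = function(args) function(name) gsub("[[:space:]]+", "_", name),
      sig = sig()),
    to_lowercase = list(
      fn = function(args) function(name) tolower(name),
      sig = sig()),
    strip_prefix = list(
      fn = function(args) {
        prefix <- args[[1L]]
        function(name) if (startsWith(name, prefix))
          substring(name, nchar(prefix) + 1L) else name
      },
      sig = sig(1L, 1L, "string"))
  )
}

# ---- user extension -------------------------------------------------------

#' Register a user-defined condition or action
#'
#' The callable is invoked as `fun(path, ...)` with the node's path and the
#' literal arguments from the recipe. User conditions are containment-
#' wrapped: an error inside one makes the condition evaluate `FALSE` and
#' journals a warning instead of aborting the run. Built-in names cannot be
#' shadowed.
#'
#' @param registry an [default_registry()] object (modified in place and
#'   returned).
#' @param role `"condition"` or `"action"`.
#' @param name symbol name usable from recipes.
#' @param fun the callable.
#' @param signature argument bounds, e.g. `list(min = 0, max = 2,
#'   type = "string")`.
#' @return the registry, invisibly.
#' @export
register_user_symbol <- function(registry, role, name, fun,
                                 signature = list(min = 0, max = 0,
                                                  type = "string")) {
  role <- match.arg(role, c("condition", "action"))
  stopifnot(is_scalar_string(name), is.function(fun))
  tab <- paste0(role, "s")
  existing <- registry[[tab]][[name]]
  if (!is.null(existing) && !isTRUE(existing$user)) {
    stop("cannot redefine built-in ", role, " '", name, "'", call. = FALSE)
  }
  s <- sig(signature$min %||% 0L, signature$max %||% signature$min %||% 0L,
           signature$type %||% "string")
  factory <- if (role == "condition") {
    function(args) function(node, ctx) {
      tryCatch(isTRUE(do.call(fun, c(list(node$path), args))),
               error = function(e) {
                 journal_add(ctx, "warn", node$rel,
                             paste0("user condition '", name, "' errored: ",
                                    conditionMessage(e)))
                 FALSE
               })
    }
  } else {
    function(args) function(node, ctx) {
      tryCatch({
        do.call(fun, c(list(node$path), args))
        invisible(NULL)
      }, error = function(e) {
        journal_add(ctx, "error", node$rel,
                    paste0("user action '", name, "' errored: ",
                           conditionMessage(e)))
        invisible(NULL)
      })
    }
  }
  registry[[tab]][[name]] <- list(fn = factory, sig = s, user = TRUE)
  invisible(registry)
}
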