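# The traversal engine. Nodes are filesystem entries below the input root;
# the root itself is not a node and its immediate children have depth 1.
# Sibling order is lexicographic by byte value — that ordering, not
# filesystem enumeration order, defines "left to right" and makes runs
# reproducible across platforms. A level-specific rule beats the "any"
# rule; a node with no applicable rule is still visited (and still
# observed by every aggregator).

#' Enumerate a directory tree as an ordered node sequence
#'
#' `topdown` yields each directory before its contents, `bottomup` after;
#' sibling order is bytewise in both. Hidden entries are yielded —
#' conditions decide relevance, not the walker.
#'
#' @param root existing directory.
#' @param order `"topdown"` or `"bottomup"`.
#' @return list of nodes: `list(path, rel, depth, kind, index)`.
#' @export
walk_tree <- function(root, order = c("topdown", "bottomup")) {
  order <- match.arg(order)
  if (!dir.exists(root)) {
    stop("input root does not exist or is not a directory: ", root,
         call. = FALSE)
  }
  root <- normalizePath(root, winslash = "/")
  out <- new.env(parent = emptyenv())
  out$nodes <- vector("list", 64L)
  out$n <- 0L
  emit <- function(path, rel, depth, kind) {
    out$n <- out$n + 1L
    if (out$n > length(out$nodes)) {
      out$nodes <- c(out$nodes, vector("list", length(out$nodes)))
    }
    out$nodes[[out$n]] <- list(path = path, rel = rel, depth = depth,
                               kind = kind, index = out$n)
  }
  recurse <- function(dir, relbase, depth) {
    entries <- byte_sort(list.files(dir, all.files = TRUE, no.. = TRUE))
    for (e in entries) {
      p <- file.path(dir, e)
      r <- if (nzchar(relbase)) paste0(relbase, "/", e) else e
      if (dir.exists(p)) {
        if (order == "topdown") {
          emit(p, r, depth, "directory")
          recurse(p, r, depth + 1L)
        } else {
          recurse(p, r, depth + 1L)
          emit(p, r, depth, "directory")
        }
      } else {
        emit(p, r, depth, "file")
      }
    }
  }
  recurse(root, "", 1L)
  out$nodes[seq_len(out$n)]
}

#' Select the rule applying to a node
#'
#' Returns the compiled rule for the node's depth if the template has one,
#' else the `any` fallback, else `NULL` (the node is ignored by rules but
#' still counted as visited and offered to aggregators).
#'
#' @param template an `rfs_template`.
#' @param node a node from [walk_tree()].
#' @return a compiled rule or `NULL`.
#' @export
dispatch_rule <- function(template, node) {
  template$by_level[[as.character(node$depth)]] %||% template$fallback
}

# ---- run context ----------------------------------------------------------

# One context per worker: private journal, private aggregator shards,
# private list collections and counters. Only the quit/abort flags are
# shared between workers (the "signal" of the early-exit contract).
new_worker_ctx <- function(template, root, shared, worker_id, opts) {
  ctx <- new.env(parent = emptyenv())
  ctx$config <- template$config
  ctx$template <- template
  ctx$root <- root
  ctx$base_dir <- dirname(root)
  ctx$worker <- worker_id
  ctx$shared <- shared
  ctx$journal <- vector("list", 32L)
  ctx$jn <- 0L
  ctx$walk_index <- 0L
  ctx$action_seq <- 0L
  ctx$current_scope <- ""
  ctx$current_passed <- NA
  ctx$visited <- 0L
  ctx$failures <- 0L
  ctx$lists <- list()
  ctx$dry_run <- isTRUE(opts$dry_run)
  ctx$allow_destructive <- isTRUE(opts$allow_destructive)
  ctx$quiet <- !isFALSE(opts$quiet)
  ctx$quarantine_dir <- opts$quarantine_dir
  ctx$shards <- lapply(template$aggregators, function(a)
    new_shard(worker_id, a$reducer, agg_params(a)))
  ctx
}

agg_params <- function(a) {
  list(name = a$name, sort_key = a$sort_key,
       threshold_a = a$threshold_a, threshold_b = a$threshold_b)
}

# Offer one node to a named aggregator. Rules never gate this: every
# visited node is offered to every aggregator, filtered only by the
# aggregator's own condition (force = TRUE bypasses it, for the
# add_to_aggregator action). A failing mapper skips the contribution with
# a journaled warning instead of killing the run.
aggregator_offer <- function(ctx, name, node, force = FALSE) {
  a <- ctx$template$aggregators[[name]]
  if (is.null(a)) {
    stop("unknown aggregator '", name, "'", call. = FALSE)
  }
  if (!force && !a$filter(node, ctx)) return(invisible(FALSE))
  node$sort_key <- extract_sort_key(node, a$sort_key)
  elem <- tryCatch(a$mapper(node, ctx), error = function(e) {
    journal_add(ctx, "warn", node$rel,
                paste0("aggregator '", name, "' could not map node: ",
                       conditionMessage(e)))
    NULL
  })
  if (is.null(elem)) return(invisible(FALSE))
  shard_add(ctx$shards[[name]], a$reducer, elem, agg_params(a))
  invisible(TRUE)
}

# Sort key of a node: a regex capture group over the file name when the
# aggregator declares one, else the relative path (unique and naturally
# sortable for z1/z2/z10-style conventions).
extract_sort_key <- function(node, pattern) {
  if (is.null(pattern)) return(node$rel)
  m <- regexec(pattern, basename(node$path), perl = TRUE)[[1L]]
  if (m[[1L]] == -1L) return(node$rel)
  parts <- regmatches(basename(node$path), list(m))[[1L]]
  if (length(parts) >= 2L) parts[[2L]] else parts[[1L]]
}

#' Apply a compiled rule to one node
#'
#' The predicate is evaluated once; on success the action sequence runs in
#' recipe order, on failure the counteraction sequence. A `quit` (or a
#' `quit_on_fail` reached on the failure path) stops the sequence and
#' signals early exit. A node whose predicate fails and whose rule
#' declares no counteractions counts as a validation failure.
#'
#' @param rule compiled rule from [dispatch_rule()].
#' @param node the node under evaluation.
#' @param ctx the run context owning the journal.
#' @return `"quit"` or `"proceed"`.
#' @keywords internal
apply_rule <- function(rule, node, ctx) {
  ctx$current_scope <- rule$scope
  passed <- rule$predicate(node, ctx)
  ctx$current_passed <- passed
  if (!passed && rule$counts_failures) {
    ctx$failures <- ctx$failures + 1L
    journal_add(ctx, "warn", node$rel,
                paste0("validation failure at ", rule$scope))
  }
  todo <- if (passed) rule$on_success else rule$on_failure
  for (act in todo) {
    res <- act(node, ctx)
    if (identical(res, "quit")) return("quit")
  }
  "proceed"
}

process_node <- function(node, ctx) {
  ctx$walk_index <- node$index
  ctx$action_seq <- 0L
  ctx$visited <- ctx$visited + 1L
  if (!file.exists(node$path) && !dir.exists(node$path)) {
    journal_add(ctx, "warn", node$rel, "node vanished before dispatch")
    return("proceed")
  }
  for (nm in names(ctx$template$aggregators)) {
    aggregator_offer(ctx, nm, node)
  }
  rule <- dispatch_rule(ctx$template, node)
  ctx$current_scope <- if (is.null(rule)) "" else rule$scope
  if (is.null(rule)) return("proceed")
  apply_rule(rule, node, ctx)
}

# ---- execution ------------------------------------------------------------

#' Execute a compiled template
#'
#' Walks the input tree in the configured order, dispatches the
#' depth-appropriate rule to every node, offers every node to every
#' aggregator, honours early exit, finalizes aggregates exactly once and
#' writes sinks. With `workers > 1` the run uses the sharded scheduler of
#' [execute_parallel()].
#'
#' @param template an `rfs_template` from [compile_template()].
#' @param input input root override; default is the recipe's `input_root`
#'   resolved against the recipe file's directory.
#' @param workers worker count; `NULL` means 1, or 4 when the recipe sets
#'   `parallel = true`.
#' @param dry_run journal all effects but mutate nothing and write no file
#'   sinks.
#' @param allow_destructive second key for real deletion (the recipe's
#'   `destructive_allowed` is the first); otherwise `remove` quarantines.
#' @param quiet suppress `show` output and stdout sink lines.
#' @param schedule_seed seed for the parallel scheduler's interleaving
#'   (ignored for serial runs); any value yields the same finalized
#'   results for schedule-independent recipes.
#' @return object of class `rfs_result`: `status` (`ok`,
#'   `validation_failures` or `aborted`), `visited_count`,
#'   `failure_count`, the canonicalized `journal`, finalized `aggregates`,
#'   collected `lists`, and `sinks` written.
#' @export
execute_template <- function(template, input = NULL, workers = NULL,
                             dry_run = FALSE, allow_destructive = FALSE,
                             quiet = TRUE, schedule_seed = NULL) {
  stopifnot(inherits(template, "rfs_template"))
  if (is.null(workers)) {
    workers <- if (isTRUE(template$config$parallel)) 4L else 1L
  }
  workers <- as.integer(workers)
  if (is.na(workers) || workers < 1L) {
    stop("workers must be >= 1", call. = FALSE)
  }
  root <- input %||% resolve_path(template$config$input_root,
                                  template$base_dir)
  if (!dir.exists(root)) {
    stop("input root does not exist or is not a directory: ", root,
         call. = FALSE)
  }
  root <- normalizePath(root, winslash = "/")
  opts <- list(
    dry_run = dry_run, allow_destructive = allow_destructive, quiet = quiet,
    quarantine_dir = resolve_path(
      template$config$quarantine_dir %||%
        paste0(basename(root), ".quarantine"),
      dirname(root))
  )
  shared <- new.env(parent = emptyenv())
  shared$quit <- FALSE
  shared$aborted <- FALSE

  nodes <- walk_tree(root, template$config$traversal_order)
  ctxs <- run_sharded(template, root, shared, nodes, workers, opts,
                      schedule_seed)
  finalize_run(template, root, ctxs, shared, opts)
}

#' Execute a template across worker shards
#'
#' Implements the lock-free contract: nodes are partitioned round-robin in
#' walk order across `workers` shards; each worker owns a private journal,
#' private aggregator accumulators and private counters, processes its
#' nodes in walk order, and shares nothing mutable with other workers
#' during the run. Cross-worker interleaving is arbitrary (driven by
#' `schedule_seed`); shards are merged exactly once at completion. For the
#' commutative/associative reducers and canonically ordered sinks and
#' journals, the finalized result is identical to a serial run. Early exit
#' is best-effort in parallel mode: after a `quit` is observed no further
#' node is scheduled on any worker, but the set of nodes already processed
#' depends on the schedule (a documented, weaker contract than serial).
#'
#' @inheritParams execute_template
#' @param workers number of shards (>= 1).
#' @return an `rfs_result`, as [execute_template()].
#' @export
execute_parallel <- function(template, workers, input = NULL,
                             dry_run = FALSE, allow_destructive = FALSE,
                             quiet = TRUE, schedule_seed = NULL) {
  execute_template(template, input = input, workers = workers,
                   dry_run = dry_run, allow_destructive = allow_destructive,
                   quiet = quiet, schedule_seed = schedule_seed)
}

run_sharded <- function(template, root, shared, nodes, workers, opts,
                        schedule_seed) {
  ctxs <- lapply(seq_len(workers), function(w)
    new_worker_ctx(template, root, shared, w, opts))
  if (length(nodes) == 0L) return(ctxs)
  assignment <- (seq_along(nodes) - 1L) %% workers + 1L
  queues <- lapply(seq_len(workers), function(w) which(assignment == w))
  heads <- rep(1L, workers)
  pick_stream <- schedule_stream(schedule_seed, length(nodes), workers)
  repeat {
    live <- which(vapply(seq_len(workers), function(w)
      heads[[w]] <= length(queues[[w]]), TRUE))
    if (length(live) == 0L || isTRUE(shared$quit)) break
    w <- live[[pick_stream(length(live))]]
    node <- nodes[[queues[[w]][[heads[[w]]]]]]
    heads[[w]] <- heads[[w]] + 1L
    res <- process_node(node, ctxs[[w]])
    if (identical(res, "quit")) shared$quit <- TRUE
  }
  ctxs
}

# Deterministic scheduling stream isolated from the global RNG. Serial
# runs (workers == 1) never consult it, so they are seed-independent.
schedule_stream <- function(seed, n, workers) {
  if (workers == 1L) return(function(k) 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed %||% 0L)
  draws <- stats::runif(n + workers + 1L)
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  } else if (exists(".Random.seed", envir = globalenv())) {
    rm(".Random.seed", envir = globalenv())
  }
  i <- 0L
  function(k) {
    i <<- i + 1L
    as.integer(floor(draws[[i]] * k)) + 1L
  }
}

finalize_run <- function(template, root, ctxs, shared, opts) {
  journal <- canonicalize_journal(
    journal_df(do.call(c, lapply(ctxs, function(c)
      c$journal[seq_len(c$jn)]))))
  visited <- sum(vapply(ctxs, `[[`, 0L, "visited"))
  failures <- sum(vapply(ctxs, `[[`, 0L, "failures"))

  lists <- list()
  for (ctx in ctxs) {
    for (nm in names(ctx$lists)) {
      lists[[nm]] <- c(lists[[nm]], ctx$lists[[nm]])
    }
  }
  lists <- lapply(lists, byte_sort)

  aggregates <- list()
  sinks <- character(0)
  for (nm in names(template$aggregators)) {
    a <- template$aggregators[[nm]]
    shards <- lapply(ctxs, function(c) c$shards[[nm]])
    value <- merge_shards(shards, a$reducer, agg_params(a))
    aggregates[[nm]] <- value
    note <- attr(value, "note")
    if (!is.null(note)) {
      journal <- rbind(journal, data.frame(
        walk_index = visited, action_seq = 9999L, path = "",
        rule_scope = "", effect_kind = "warn",
        detail = paste0("aggregator '", nm, "': ", note),
        stringsAsFactors = FALSE))
    }
    if (a$sink$kind == "stdout") {
      if (!isTRUE(opts$quiet)) write_sink(value, a$sink, dirname(root), nm)
    } else if (!isTRUE(opts$dry_run)) {
      dest <- write_sink(value, a$sink, dirname(root), nm)
      sinks[[nm]] <- dest
    }
  }

  status <- if (isTRUE(shared$aborted)) "aborted"
            else if (failures > 0L) "validation_failures"
            else "ok"
  structure(
    list(status = status, visited_count = visited,
         failure_count = failures, journal = journal,
         aggregates = aggregates, lists = lists, sinks = sinks,
         quit = isTRUE(shared$quit), root = root),
    class = "rfs_result")
}

#' @export
print.rfs_result <- function(x, ...) {
  cat("<rfs_result> status:", x$status,
      "| visited:", x$visited_count,
      "| failures:", x$failure_count,
      "| journal entries:", nrow(x$journal), "\n")
  for (nm in names(x$aggregates)) {
    cat("  ", format_aggregate(nm, x$aggregates[[nm]]), "\n", sep = "")
  }
  invisible(x)
}
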