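# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the flood fill is queue-based (the package
# labels with two-pass union-find), the tree enumerator is plain recursive
# list.files, and the composite evaluator works on a truth assignment
# instead of compiled closures.

# queue-based flood fill, 8-connectivity; returns component sizes sorted
# decreasing
oracle_flood_sizes <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  sizes <- integer(0)
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j] || seen[i, j]) next
      queue <- list(c(i, j))
      seen[i, j] <- TRUE
      size <- 0L
      while (length(queue) > 0L) {
        p <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        size <- size + 1L
        for (di in -1:1) for (dj in -1:1) {
          if (di == 0L && dj == 0L) next
          y <- p[[1L]] + di
          x <- p[[2L]] + dj
          if (y >= 1L && y <= nr && x >= 1L && x <= nc &&
              mask[y, x] && !seen[y, x]) {
            seen[y, x] <- TRUE
            queue[[length(queue) + 1L]] <- c(y, x)
          }
        }
      }
      sizes <- c(sizes, size)
    }
  }
  sort(sizes, decreasing = TRUE)
}

# independent recursive enumeration of all entries under root
oracle_enumerate <- function(root) {
  out <- character(0)
  rec <- function(dir, rel) {
    for (e in list.files(dir, all.files = TRUE, no.. = TRUE)) {
      r <- if (nzchar(rel)) paste0(rel, "/", e) else e
      out <<- c(out, r)
      p <- file.path(dir, e)
      if (dir.exists(p)) rec(p, r)
    }
  }
  rec(root, "")
  sort(out, method = "radix")
}

# ---- random boolean composites vs a truth-table oracle --------------------

composite_leaves <- list(
  list(name = "is_file", args = list(),
       truth = function(p) file.exists(p) && !dir.exists(p)),
  list(name = "is_dir", args = list(),
       truth = function(p) dir.exists(p)),
  list(name = "is_hidden", args = list(),
       truth = function(p) startsWith(basename(p), ".")),
  list(name = "has_extension", args = list(".txt"),
       truth = function(p) grepl("\\.txt$", tolower(basename(p)))),
  list(name = "has_extension", args = list(".tif"),
       truth = function(p) grepl("\\.tif$", tolower(basename(p)))),
  list(name = "has_extension", args = list(".csv"),
       truth = function(p) grepl("\\.csv$", tolower(basename(p)))),
  list(name = "name_is_integer", args = list(),
       truth = function(p) grepl("^[0-9]+$", sub("\\.[^.]*$", "", basename(p)))),
  list(name = "always", args = list(), truth = function(p) TRUE),
  list(name = "never", args = list(), truth = function(p) FALSE)
)

# builds list(expr = rfs symbol expression, truth = function(path) flag)
random_composite <- function(rng, depth) {
  if (depth <= 0L || rng$unif() < 0.35) {
    leaf <- composite_leaves[[rng$int(1L, length(composite_leaves))]]
    negated <- rng$unif() < 0.5
    expr <- recipefs:::new_symbol(leaf$name, leaf$args, negated = negated)
    truth <- if (negated) function(p) !leaf$truth(p) else leaf$truth
    return(list(expr = expr, truth = truth))
  }
  op <- c("all_of", "any_of", "not")[[rng$int(1L, 3L)]]
  if (op == "not") {
    sub <- random_composite(rng, depth - 1L)
    return(list(expr = compose("not", list(sub$expr)),
                truth = function(p) !sub$truth(p)))
  }
  k <- rng$int(2L, 3L)
  subs <- lapply(seq_len(k), function(i) random_composite(rng, depth - 1L))
  expr <- compose(op, lapply(subs, `[[`, "expr"))
  truth <- if (op == "all_of") {
    function(p) all(vapply(subs, function(s) s$truth(p), TRUE))
  } else {
    function(p) any(vapply(subs, function(s) s$truth(p), TRUE))
  }
  list(expr = expr, truth = truth)
}

# evaluate a condition symbol the way the engine would, on a bare node
compiled_condition_value <- function(expr, path) {
  fn <- recipefs:::compile_condition(expr, list(), default_registry())
  node <- list(path = path, rel = basename(path),
               depth = 1L, kind = if (dir.exists(path)) "directory" else "file")
  ctx <- recipefs:::new_worker_ctx(
    structure(list(config = list(regex_enabled = FALSE), aggregators = list()),
              class = "rfs_template"),
    dirname(path), new.env(), 1L, list())
  fn(node, ctx)
}

# deterministic helper rng decoupled from .Random.seed
helper_rng <- function(seed) recipefs:::fixture_rng(seed)

# tiny literal tree builder: names ending in "/" are directories
build_tree <- function(root, entries) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (e in entries) {
    p <- file.path(root, sub("/$", "", e))
    if (endsWith(e, "/")) {
      dir.create(p, recursive = TRUE, showWarnings = FALSE)
    } else {
      dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
      writeLines(e, p)
    }
  }
  invisible(root)
}

recipe_text <- function(...) paste(c(...), collapse = "\n")

run_recipe_text <- function(text, input, ...) {
  doc <- parse_recipe(text)
  execute_template(compile_template(doc), input = input, ...)
}
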