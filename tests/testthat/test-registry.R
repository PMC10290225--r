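# Predicates are exercised through compiled recipes (the public path) on
# literal trees whose expected outcome is hand-countable.

select_with <- function(condition_toml, root, extra_global = character(0)) {
  res <- run_recipe_text(recipe_text(
    '[global]', 'input_root = "d"', extra_global,
    '[template.any]',
    paste0('conditions = [', condition_toml, ']'),
    'actions = [["add_to_list", "hit"]]',
    'counteractions = [["add_to_list", "miss"]]'), root)
  res$lists$hit %||% character(0)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("extension matching is case-insensitive, name matching is not", {
  root <- build_tree(tempfile(),
                     c("cell_01.TIF", "cell_02.tif", "notes.txt"))
  expect_setequal(select_with('["has_extension", ".tif"]', root),
                  c("cell_01.TIF", "cell_02.tif"))
  # literal (substring) mode is case-sensitive
  expect_setequal(select_with('["name_matches", "cell"]', root),
                  c("cell_01.TIF", "cell_02.tif"))
  expect_length(select_with('["name_matches", "CELL"]', root), 0)
  # regex mode anchors and classes work
  expect_setequal(
    select_with('["name_matches", "^cell_[0-9]+[.]tif$"]', root,
                'regex_enabled = true'),
    "cell_02.tif")
})

test_that("content conditions inspect image dimensionality and csv schema", {
  root <- tempfile()
  dir.create(root)
  generate_image(c(5L, 4L, 4L), "constant", value = 3,
                 path = file.path(root, "vol.tif"))
  generate_image(c(6L, 6L), "constant", value = 3,
                 path = file.path(root, "flat.png"))
  write.csv(data.frame(x = 1, y = 2, z = 3), file.path(root, "good.csv"),
            row.names = FALSE)
  write.csv(data.frame(x = 1, z = 3), file.path(root, "bad.csv"),
            row.names = FALSE)
  writeLines("text", file.path(root, "plain.txt"))

  expect_setequal(select_with('["image_has_dims", "3"]', root), "vol.tif")
  expect_setequal(select_with('["image_has_dims", "2"]', root), "flat.png")
  expect_setequal(select_with('["csv_has_columns", "x", "y"]', root),
                  "good.csv")
  expect_setequal(select_with('["csv_has_columns", "x"]', root),
                  c("good.csv", "bad.csv"))
  expect_setequal(select_with('"is_image"', root),
                  c("vol.tif", "flat.png"))
})

test_that("size, naming and structural predicates behave on a known tree", {
  root <- build_tree(tempfile(), c("12.txt", "x1/", "x1/deep.txt",
                                   ".hidden"))
  writeBin(raw(400), file.path(root, "big.bin"))
  writeBin(raw(0), file.path(root, "empty.bin"))
  expect_setequal(select_with('["size_at_least", "400"]', root), "big.bin")
  expect_setequal(select_with('["size_at_most", "0"]', root), "empty.bin")
  expect_setequal(select_with('"name_is_integer"', root), "12.txt")
  expect_setequal(select_with('"is_hidden"', root), ".hidden")
  expect_setequal(select_with('["all_of", "is_file", ["path_depth_is", "2"]]',
                              root), "x1/deep.txt")
  expect_setequal(select_with('"is_dir"', root), "x1")
  expect_length(select_with('"never"', root), 0)
})

test_that("rename transforms compose left to right", {
  root <- build_tree(tempfile(), character(0))
  file.create(file.path(root, "My Data.TIF"))
  file.create(file.path(root, "IMG_keep.txt"))
  res <- run_recipe_text(recipe_text(
    '[global]', 'input_root = "d"',
    '[template.any]',
    'conditions = ["is_file"]',
    'actions = [["rename", "whitespace_to_underscore", "to_lowercase"]]'),
    root)
  expect_setequal(list.files(root), c("my_data.tif", "img_keep.txt"))

  res2 <- run_recipe_text(recipe_text(
    '[global]', 'input_root = "d"',
    '[template.any]',
    'conditions = ["is_file"]',
    'actions = [["rename", ["strip_prefix", "img_"]]]'), root)
  expect_true("keep.txt" %in% list.files(root))
})

test_that("remove quarantines by default and the quarantine is reversible", {
  root <- build_tree(tempfile(), c("a/", "a/junk.tmp", "a/keep.txt",
                                   "top.tmp"))
  before <- tree_hash(root)
  res <- run_recipe_text(recipe_text(
    '[global]', 'input_root = "d"',
    '[template.any]',
    'conditions = [["has_extension", ".tmp"]]',
    'actions = ["remove"]',
    'counteractions = [["add_to_list", "kept"]]'), root)
  q <- paste0(root, ".quarantine")
  expect_setequal(list.files(q, recursive = TRUE),
                  c("a/junk.tmp", "top.tmp"))
  expect_false(file.exists(file.path(root, "top.tmp")))
  expect_equal(sum(res$journal$effect_kind == "quarantine"), 2)
  # restoring quarantined content reproduces the original tree
  for (f in list.files(q, recursive = TRUE)) {
    dir.create(dirname(file.path(root, f)), recursive = TRUE,
               showWarnings = FALSE)
    file.rename(file.path(q, f), file.path(root, f))
  }
  expect_identical(tree_hash(root), before)
})

test_that("real deletion needs the recipe flag AND the run option", {
  mk <- function() build_tree(tempfile(), c("junk.tmp", "keep.txt"))
  text <- recipe_text(
    '[global]', 'input_root = "d"', 'destructive_allowed = true',
    '[template.any]',
    'conditions = [["has_extension", ".tmp"]]',
    'actions = ["remove"]',
    'counteractions = [["add_to_list", "kept"]]')
  r1 <- mk()
  run_recipe_text(text, r1)                       # no CLI opt-in
  expect_true(file.exists(file.path(paste0(r1, ".quarantine"), "junk.tmp")))
  r2 <- mk()
  res <- run_recipe_text(text, r2, allow_destructive = TRUE)
  expect_false(file.exists(file.path(r2, "junk.tmp")))
  expect_false(dir.exists(paste0(r2, ".quarantine")))
  expect_equal(sum(res$journal$effect_kind == "delete"), 1)
})

test_that("flatten derives names from paths; copy collisions get suffixes", {
  root <- build_tree(tempfile(), c("a/", "b/", "a/c.tif", "b/c.tif"))
  res <- run_recipe_text(recipe_text(
    '[global]', 'input_root = "d"',
    '[template.any]',
    'conditions = [["has_extension", ".tif"]]',
    'actions = [["flatten_to", "flat"]]',
    'counteractions = [["add_to_list", "skip"]]'), root)
  flat <- file.path(dirname(root), "flat")
  expect_setequal(list.files(flat), c("a_c.tif", "b_c.tif"))
  expect_equal(sum(res$journal$effect_kind == "copy"), 2)

  # copy_to with equal basenames: second file gets _1 before the extension
  root2 <- build_tree(tempfile(), c("a/", "b/", "a/c.tif", "b/c.tif"))
  run_recipe_text(recipe_text(
    '[global]', 'input_root = "d"',
    '[template.any]',
    'conditions = [["has_extension", ".tif"]]',
    'actions = [["copy_to", "merged"]]',
    'counteractions = [["add_to_list", "skip"]]'), root2)
  expect_setequal(list.files(file.path(dirname(root2), "merged")),
                  c("c.tif", "c_1.tif"))
})

test_that("conditions never mutate: a log-only recipe leaves the tree intact", {
  root <- tempfile()
  generate_tree(tree_spec(seed = 11), root)
  before <- tree_hash(root)
  run_recipe_text(recipe_text(
    '[global]', 'input_root = "d"',
    '[template.any]',
    'conditions = [["any_of", "is_dir", "is_image", "is_csv", "always"]]',
    'actions = ["show"]',
    'counteractions = ["warn"]'), root)
  expect_identical(tree_hash(root), before)
})

test_that("the journal accounts for every filesystem mutation", {
  root <- build_tree(tempfile(), c("a/", "a/one.txt", "a/two.txt", "im.tif"))
  before <- oracle_enumerate(root)
  res <- run_recipe_text(recipe_text(
    '[global]', 'input_root = "d"',
    '[template.any]',
    'conditions = [["has_extension", ".txt"]]',
    'actions = [["move_to", "moved"]]',
    'counteractions = [["add_to_list", "skip"]]'), root)
  after <- oracle_enumerate(root)
  gone <- setdiff(before, after)
  moved_rows <- res$journal[res$journal$effect_kind == "move", ]
  expect_setequal(gone, moved_rows$path)
  expect_setequal(list.files(file.path(dirname(root), "moved")),
                  basename(moved_rows$path))
})

test_that("user symbols register, fire, and are containment-wrapped", {
  reg <- default_registry()
  register_user_symbol(reg, "condition", "is_even_size",
                       function(path) file.size(path) %% 2 == 0)
  expect_error(register_user_symbol(reg, "condition", "is_file", identity),
               "redefine built-in")

  root <- build_tree(tempfile(), character(0))
  writeBin(raw(4), file.path(root, "even.bin"))
  writeBin(raw(5), file.path(root, "odd.bin"))
  doc <- parse_recipe(recipe_text(
    '[global]', 'input_root = "d"',
    '[template.any]',
    'conditions = ["is_even_size"]',
    'actions = [["add_to_list", "even"]]',
    'counteractions = [["add_to_list", "odd"]]'))
  expect_length(validate_document(doc, reg), 0)
  res <- execute_template(compile_template(doc, reg), input = root)
  expect_identical(res$lists$even, "even.bin")
  expect_identical(res$lists$odd, "odd.bin")

  # a raising user condition evaluates FALSE, journals, and the run completes
  register_user_symbol(reg, "condition", "explodes",
                       function(path) stop("boom"))
  doc2 <- parse_recipe(recipe_text(
    '[global]', 'input_root = "d"',
    '[template.any]',
    'conditions = ["explodes"]',
    'actions = [["add_to_list", "hit"]]',
    'counteractions = [["add_to_list", "miss"]]'))
  res2 <- execute_template(compile_template(doc2, reg), input = root)
  expect_equal(res2$visited_count, 2)
  expect_length(res2$lists$hit %||% character(0), 0)
  expect_true(any(grepl("boom", res2$journal$detail)))
})

test_that("compose builds resolvable composites obeying boolean laws", {
  root <- build_tree(tempfile(), c("x.png", "y.csv", "d/"))
  nodes <- file.path(root, c("x.png", "y.csv", "d"))
  e1 <- compose("all_of", list(
    "is_file", compose("any_of", list(
      recipefs:::new_symbol("has_extension", list(".tif")),
      recipefs:::new_symbol("has_extension", list(".png"))))))
  vals <- vapply(nodes, function(p) compiled_condition_value(e1, p), TRUE)
  expect_identical(unname(vals), c(TRUE, FALSE, FALSE))

  dn <- compose("not", list(compose("not", list("is_file"))))
  for (p in nodes) {
    expect_identical(compiled_condition_value(dn, p),
                     compiled_condition_value(
                       recipefs:::new_symbol("is_file"), p))
  }
  expect_error(compose("not", list("is_file", "is_dir")), "exactly one")
  expect_error(compose("all_of", list()), "non-empty")
})

test_that("random composites agree with an independent truth-table oracle", {
  root <- tempfile()
  generate_tree(tree_spec(naming = "messy", seed = 23), root)
  paths <- file.path(root, oracle_enumerate(root))
  rng <- helper_rng(99)
  for (i in 1:120) {
    comp <- random_composite(rng, depth = 4L)
    for (p in paths) {
      expect_identical(compiled_condition_value(comp$expr, p),
                       comp$truth(p),
                       label = paste("composite", i, "on", basename(p)))
    }
  }
})
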