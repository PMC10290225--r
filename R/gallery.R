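# The example-recipe gallery. Every shipped recipe is exercised end-to-end
# by the automated tests against a seeded scenario fixture whose ground
# truth is known by construction; the helpers here are shared by the test
# suite and by scripts/acceptance.R so both run the same scenarios.

#' Locate the shipped recipe gallery
#'
#' @return path of the installed gallery directory.
#' @export
gallery_dir <- function() {
  system.file("recipes", "gallery", package = "recipefs")
}

#' List the shipped gallery recipes
#'
#' @return character vector of recipe file names (sorted).
#' @export
gallery_recipes <- function() {
  byte_sort(list.files(gallery_dir(), pattern = "\\.toml$"))
}

#' Scenario fixture a gallery recipe runs against
#'
#' Keyed by the recipe file's numeric prefix.
#'
#' @param recipe_name file name from [gallery_recipes()].
#' @return scenario name for [gallery_fixture()].
#' @export
gallery_scenario <- function(recipe_name) {
  n <- as.integer(sub("^([0-9]+)_.*$", "\\1", recipe_name))
  if (n %in% c(10L, 12L:17L, 26L, 32L)) return("messy")
  if (n %in% c(22L)) return("integers")
  if (n %in% c(24L, 25L)) return("duplicates")
  if (n %in% c(27L, 28L)) return("scratchfiles")
  if (n %in% 34L:39L) return("imaging")
  if (n %in% 40L:41L) return("tables")
  "standard"
}

#' Build the fixture tree for a gallery scenario
#'
#' Scenarios: `standard` and `messy` are [generate_tree()] trees (clean /
#' with planted violations); `imaging` holds z-slices, blob images, a
#' two-channel pair and a 3D time series with analytically known content;
#' `tables` holds CSVs sharing one header; `duplicates`, `integers` and
#' `scratchfiles` are small hand-shaped trees for the flatten/move,
#' integer-naming and quarantine recipes.
#'
#' @param scenario scenario name.
#' @param dir destination directory (must not exist yet or be empty).
#' @param seed fixture seed.
#' @return ground-truth description; a manifest data.frame for the
#'   generated scenarios, a named list for the hand-shaped ones.
#' @export
gallery_fixture <- function(scenario, dir, seed = 1L) {
  switch(scenario,
    standard = generate_tree(tree_spec(seed = seed), dir),
    messy = generate_tree(tree_spec(naming = "messy", seed = seed), dir),
    imaging = imaging_fixture(dir),
    tables = tables_fixture(dir),
    duplicates = duplicates_fixture(dir),
    integers = integers_fixture(dir),
    scratchfiles = scratchfiles_fixture(dir),
    stop("unknown gallery scenario '", scenario, "'", call. = FALSE))
}

#' Run one gallery recipe against its scenario fixture
#'
#' Builds the scenario tree under a private workspace, executes the recipe
#' against it and returns everything a check needs: the run result, the
#' fixture ground truth, and the paths involved.
#'
#' @param recipe_name file name from [gallery_recipes()].
#' @param workspace directory to build the fixture in (created; a fresh
#'   `tempfile()` by default).
#' @param seed fixture seed.
#' @param workers,schedule_seed,dry_run,allow_destructive,quiet passed to
#'   [execute_template()].
#' @return list with `result`, `truth`, `root` (the input tree),
#'   `workspace` and `recipe` (the parsed document).
#' @export
gallery_run <- function(recipe_name, workspace = tempfile("gallery_"),
                        seed = 1L, workers = NULL, schedule_seed = NULL,
                        dry_run = FALSE, allow_destructive = FALSE,
                        quiet = TRUE) {
  path <- file.path(gallery_dir(), recipe_name)
  if (!file.exists(path)) {
    stop("no such gallery recipe: ", recipe_name, call. = FALSE)
  }
  dir.create(workspace, recursive = TRUE, showWarnings = FALSE)
  root <- file.path(workspace, "data")
  truth <- gallery_fixture(gallery_scenario(recipe_name), root, seed = seed)
  doc <- read_recipe(path)
  template <- compile_template(doc)
  result <- execute_template(template, input = root, workers = workers,
                             schedule_seed = schedule_seed,
                             dry_run = dry_run,
                             allow_destructive = allow_destructive,
                             quiet = quiet)
  list(result = result, truth = truth, root = normalizePath(root, "/"),
       workspace = normalizePath(workspace, "/"), recipe = doc)
}

# ---- hand-shaped scenario trees ------------------------------------------

imaging_fixture <- function(dir) {
  # z-slices with values keyed to their natural order (z2 before z10)
  slice_values <- c(z1 = 10, z2 = 20, z10 = 100)
  for (nm in names(slice_values)) {
    generate_image(c(6L, 5L), "constant", value = slice_values[[nm]],
                   path = file.path(dir, "imgs", paste0(nm, ".tif")))
  }
  blob_counts <- c(b1 = 1L, b2 = 2L, b3 = 3L)
  blobs <- list()
  for (nm in names(blob_counts)) {
    img <- generate_image(c(12L, 14L), "blobs", n_blobs = blob_counts[[nm]],
                          seed = 100L + blob_counts[[nm]],
                          path = file.path(dir, "blobs", paste0(nm, ".tif")))
    blobs[[nm]] <- attr(img, "blobs")
  }
  ch0 <- generate_image(c(8L, 8L), "ramp")
  ch1 <- max(ch0) - ch0                       # exact inversion: r = -1
  write_image(ch0, file.path(dir, "ch", "a_ch0.tif"))
  write_image(ch1, file.path(dir, "ch", "a_ch1.tif"))
  vols <- lapply(0:3, function(t) {
    v <- array(t * 40 + seq_len(2L * 4L * 4L) %% 37, dim = c(2L, 4L, 4L))
    write_image(v, file.path(dir, "vols", paste0("t", t, ".tif")))
    read_image(file.path(dir, "vols", paste0("t", t, ".tif")))
  })
  names(vols) <- paste0("t", 0:3)
  list(slice_values = slice_values, blob_counts = blob_counts,
       blobs = blobs, ch0 = ch0, ch1 = ch1, vols = vols)
}

tables_fixture <- function(dir) {
  rows <- c(a = 3L, b = 5L, c = 2L)
  sub <- c(a = "d1", b = "d1", c = "d2")
  for (nm in names(rows)) {
    n <- rows[[nm]]
    df <- data.frame(x = seq_len(n), y = seq_len(n) * 10L)
    p <- file.path(dir, sub[[nm]], paste0(nm, ".csv"))
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(df, p, row.names = FALSE)
  }
  list(rows = rows, sub = sub, total_rows = sum(rows))
}

duplicates_fixture <- function(dir) {
  files <- c("a/c.tif", "b/c.tif", "b/d.tif", "a/note_a.txt", "b/note_b.txt")
  for (f in files) {
    p <- file.path(dir, f)
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    if (endsWith(f, ".tif")) {
      generate_image(c(4L, 4L), "constant", value = 50, path = p)
    } else {
      writeLines("note", p)
    }
  }
  list(files = files,
       tifs = files[endsWith(files, ".tif")],
       txts = files[endsWith(files, ".txt")])
}

integers_fixture <- function(dir) {
  plates <- c("1", "2", "10", "control")
  for (p in plates) {
    d <- file.path(dir, p)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    writeLines("x", file.path(d, "readme.txt"))
  }
  list(plates = plates, integer_plates = c("1", "2", "10"))
}

scratchfiles_fixture <- function(dir) {
  keep <- c("results/summary.csv", "results/final.txt")
  junk <- c("results/cache.tmp", "old.tmp", "results/deep/scratch.tmp")
  for (f in c(keep, junk)) {
    p <- file.path(dir, f)
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    writeLines(basename(f), p)
  }
  list(keep = keep, junk = junk)
}
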