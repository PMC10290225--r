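# Seeded synthetic filesystem trees with ground-truth manifests. The
# manifest — not the tree — is the testing oracle: every generated entry
# is recorded with its kind, size, content descriptor and any planted
# naming/content violation, so a recipe's observable behaviour can be
# predicted without re-reading the tree.

#' Describe a synthetic tree to generate
#'
#' @param depth directory nesting below the root (1 = files directly under
#'   the root only).
#' @param branching integer pair: min/max subdirectories per directory.
#' @param files_per_dir integer pair: min/max files per directory.
#' @param type_mix named weights over file types `opaque` (plain text),
#'   `png2d`, `tiff3d` and `csv`; normalised to sum to 1.
#' @param naming `"clean"` for well-formed names, `"messy"` to plant at
#'   least one violation of each checked family: a space in the name, an
#'   uppercase name, a double extension, a hidden file, a non-ASCII name,
#'   a 2D TIFF where 3D is expected, and a CSV missing a required column.
#' @param seed integer seed; the same spec and seed always produce the
#'   same manifest and the same bytes on disk.
#' @return object of class `rfs_treespec`.
#' @export
tree_spec <- function(depth = 2L, branching = c(1L, 2L),
                      files_per_dir = c(2L, 4L),
                      type_mix = c(opaque = 0.4, png2d = 0.2,
                                   tiff3d = 0.2, csv = 0.2),
                      naming = c("clean", "messy"), seed = 1L) {
  naming <- match.arg(naming)
  stopifnot(depth >= 1L, length(branching) == 2L, all(branching >= 0L),
            branching[[1L]] <= branching[[2L]],
            length(files_per_dir) == 2L, all(files_per_dir >= 0L),
            files_per_dir[[1L]] <= files_per_dir[[2L]],
            all(type_mix >= 0), sum(type_mix) > 0)
  missing_types <- setdiff(c("opaque", "png2d", "tiff3d", "csv"),
                           names(type_mix))
  type_mix[missing_types] <- 0
  structure(list(depth = as.integer(depth), branching = as.integer(branching),
                 files_per_dir = as.integer(files_per_dir),
                 type_mix = type_mix / sum(type_mix), naming = naming,
                 seed = as.integer(seed)),
            class = "rfs_treespec")
}

#' Generate a synthetic tree with its manifest
#'
#' Deterministic for a fixed spec and seed: identical manifests and
#' identical file bytes across runs (image encoders are pinned to
#' uncompressed output). In messy mode the planted defects are recorded in
#' the manifest's `violation` column, one defect family per defective
#' file, so a validation recipe's failure count can be predicted exactly.
#'
#' @param spec an [tree_spec()] object.
#' @param root destination directory; must be empty or absent.
#' @return the manifest: a data.frame with one row per generated entry
#'   (`path`, `kind`, `depth`, `size`, `type`, `descriptor`, `violation`),
#'   with the spec attached as attribute `"spec"`.
#' @export
generate_tree <- function(spec, root) {
  stopifnot(inherits(spec, "rfs_treespec"))
  if (dir.exists(root) && length(list.files(root, all.files = TRUE,
                                            no.. = TRUE)) > 0L) {
    stop("refusing to generate into non-empty directory: ", root,
         call. = FALSE)
  }
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  rng <- fixture_rng(spec$seed)
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  entries <- list()
  add <- function(path, kind, size, type, descriptor, violation, depth) {
    entries[[length(entries) + 1L]] <<- data.frame(
      path = path, kind = kind, depth = depth, size = size, type = type,
      descriptor = descriptor, violation = violation,
      stringsAsFactors = FALSE)
  }
  fill_dir <- function(dir, rel, depth) {
    nfiles <- rng$int(spec$files_per_dir[[1L]], spec$files_per_dir[[2L]])
    for (i in seq_len(nfiles)) {
      gen_file(dir, rel, depth, spec, rng, add, counter)
    }
    if (depth <= spec$depth - 1L) {
      ndirs <- rng$int(spec$branching[[1L]], spec$branching[[2L]])
      for (d in seq_len(ndirs)) {
        nm <- sprintf("set_%02d", d)
        sub <- file.path(dir, nm)
        dir.create(sub)
        subrel <- if (nzchar(rel)) paste0(rel, "/", nm) else nm
        add(subrel, "directory", 0, "dir", "", "none", depth)
        fill_dir(sub, subrel, depth + 1L)
      }
    }
  }
  fill_dir(root, "", 1L)
  if (spec$naming == "messy") {
    plant_violations(root, spec, rng, add)
  }
  manifest <- do.call(rbind, entries)
  manifest <- manifest[order(manifest$path, method = "radix"), , drop = FALSE]
  rownames(manifest) <- NULL
  attr(manifest, "spec") <- spec
  manifest
}

# Self-contained linear congruential generator so fixture determinism does
# not depend on (or disturb) R's global RNG state.
fixture_rng <- function(seed) {
  state <- (as.numeric(seed) + 11L) %% 2147483647
  nxt <- function() {
    state <<- (state * 48271) %% 2147483647
    state / 2147483647
  }
  list(
    unif = nxt,
    int = function(lo, hi) {
      if (hi <= lo) return(as.integer(lo))
      as.integer(lo + floor(nxt() * (hi - lo + 1)))
    },
    pick = function(weights) {
      u <- nxt()
      cs <- cumsum(weights) / sum(weights)
      names(weights)[[which(u <= cs)[[1L]]]]
    }
  )
}

# File stems carry a tree-global counter, so basenames are unique across
# directories (repeated basenames would make copy/move collision suffixes
# depend on processing order).
gen_file <- function(dir, rel, depth, spec, rng, add, counter) {
  type <- rng$pick(spec$type_mix)
  counter$n <- counter$n + 1L
  stem <- sprintf("%s_%03d", switch(type, opaque = "file", png2d = "img",
                                    tiff3d = "vol", csv = "tab"),
                  counter$n)
  relname <- function(name) if (nzchar(rel)) paste0(rel, "/", name) else name
  if (type == "opaque") {
    name <- paste0(stem, ".txt")
    path <- file.path(dir, name)
    n <- rng$int(16L, 512L)
    writeBin(charToRaw(strrep(letters[[rng$int(1L, 26L)]], n)), path)
    add(relname(name), "file", file.size(path), "opaque",
        paste0("bytes:", n), "none", depth)
  } else if (type == "png2d") {
    name <- paste0(stem, ".png")
    path <- file.path(dir, name)
    h <- rng$int(6L, 12L)
    w <- rng$int(6L, 12L)
    val <- rng$int(1L, 255L)
    generate_image(c(h, w), pattern = "constant", value = val, path = path)
    add(relname(name), "file", file.size(path), "png2d",
        sprintf("shape:%dx%d;constant:%d", h, w, val), "none", depth)
  } else if (type == "tiff3d") {
    name <- paste0(stem, ".tif")
    path <- file.path(dir, name)
    z <- rng$int(2L, 4L)
    h <- rng$int(6L, 10L)
    w <- rng$int(6L, 10L)
    nblobs <- rng$int(1L, 3L)
    desc <- generate_image(c(z, h, w), pattern = "blobs", n_blobs = nblobs,
                           seed = rng$int(1L, 10000L), path = path)
    add(relname(name), "file", file.size(path), "tiff3d",
        sprintf("shape:%dx%dx%d;blobs:%d", z, h, w, nblobs), "none", depth)
  } else {
    name <- paste0(stem, ".csv")
    path <- file.path(dir, name)
    n <- rng$int(3L, 8L)
    df <- data.frame(x = seq_len(n),
                     y = vapply(seq_len(n), function(i) rng$int(0L, 100L), 0L))
    utils::write.csv(df, path, row.names = FALSE)
    add(relname(name), "file", file.size(path), "csv",
        sprintf("header:x,y;rows:%d", n), "none", depth)
  }
}

# Fixed defect corpus, one file per family, planted at the tree root so
# every messy tree violates each checked condition family at least once.
plant_violations <- function(root, spec, rng, add) {
  plant <- function(name, family, writer, type, descriptor) {
    path <- file.path(root, name)
    writer(path)
    add(name, "file", file.size(path), type, descriptor, family, 1L)
  }
  txt <- function(path) writeBin(charToRaw("stray content\n"), path)
  plant("My Data.txt", "space", txt, "opaque", "bytes:14")
  plant("UPPER_CASE.TXT", "uppercase", txt, "opaque", "bytes:14")
  plant("archive.tar.txt", "double_extension", txt, "opaque", "bytes:14")
  plant(".hidden_notes.txt", "hidden", txt, "opaque", "bytes:14")
  plant("café.txt", "non_ascii", txt, "opaque", "bytes:14")
  plant("flat_vol.tif", "wrong_dims", function(path) {
    generate_image(c(5L, 5L), pattern = "constant", value = 9, path = path)
  }, "tiff2d", "shape:5x5;constant:9")
  plant("bad_schema.csv", "csv_schema", function(path) {
    utils::write.csv(data.frame(x = 1:3, z = 4:6), path, row.names = FALSE)
  }, "csv", "header:x,z;rows:3")
}

#' Generate a single synthetic image with a known content descriptor
#'
#' Patterns: `constant` (every pixel equals `value`), `ramp` (strictly
#' increasing values along the flattened pixel order — an analytic oracle
#' for correlation signs) and `blobs` (`n_blobs` non-touching rectangular
#' blobs of intensity 200 on a zero background, an exact oracle for object
#' counting). For a 3D shape, blobs are planted per slice.
#'
#' @param shape 2D `(y, x)` or 3D `(z, y, x)` dimensions.
#' @param pattern `"constant"`, `"ramp"` or `"blobs"`.
#' @param value constant intensity (pattern `constant`).
#' @param n_blobs blobs per slice (pattern `blobs`).
#' @param seed seed for blob placement.
#' @param path optional output file (`.tif`/`.png`); written uncompressed.
#' @return the image array, invisibly if written; attribute `"blobs"`
#'   holds a data.frame of planted blob rectangles (slice, y0, y1, x0, x1,
#'   size).
#' @export
generate_image <- function(shape, pattern = c("constant", "ramp", "blobs"),
                           value = 128, n_blobs = 2L, seed = 1L,
                           path = NULL) {
  pattern <- match.arg(pattern)
  stopifnot(length(shape) %in% c(2L, 3L), all(shape >= 1L))
  shape <- as.integer(shape)
  img <- array(0, dim = shape)
  blobs <- NULL
  if (pattern == "constant") {
    img[] <- value
  } else if (pattern == "ramp") {
    img[] <- seq(0L, length.out = length(img)) %% 256
  } else {
    rng <- fixture_rng(seed)
    nslices <- if (length(shape) == 3L) shape[[1L]] else 1L
    rows <- list()
    for (s in seq_len(nslices)) {
      hw <- if (length(shape) == 3L) shape[2:3] else shape
      placed <- place_blobs(hw, n_blobs, rng)
      for (b in placed) {
        if (length(shape) == 3L) {
          img[s, b$y0:b$y1, b$x0:b$x1] <- 200
        } else {
          img[b$y0:b$y1, b$x0:b$x1] <- 200
        }
        rows[[length(rows) + 1L]] <- data.frame(
          slice = s, y0 = b$y0, y1 = b$y1, x0 = b$x0, x1 = b$x1,
          size = (b$y1 - b$y0 + 1L) * (b$x1 - b$x0 + 1L))
      }
    }
    blobs <- do.call(rbind, rows)
  }
  if (length(shape) == 2L) img <- matrix(img, shape[[1L]], shape[[2L]])
  attr(img, "blobs") <- blobs
  if (!is.null(path)) {
    write_image(img, path)
    return(invisible(img))
  }
  img
}

# Non-touching rectangles: blobs keep a 1-pixel moat, so 8-connectivity
# can never join two of them and the planted count IS the object count.
place_blobs <- function(hw, n, rng) {
  occupied <- matrix(FALSE, hw[[1L]], hw[[2L]])
  placed <- list()
  tries <- 0L
  while (length(placed) < n) {
    tries <- tries + 1L
    if (tries > 500L) {
      stop("cannot place ", n, " non-touching blobs in a ",
           hw[[1L]], "x", hw[[2L]], " slice", call. = FALSE)
    }
    # shrink to single-pixel blobs when a crowded slice resists placement
    maxh <- if (tries > 100L) 1L else max(1L, min(3L, hw[[1L]] %/% 2L))
    maxw <- if (tries > 100L) 1L else max(1L, min(3L, hw[[2L]] %/% 2L))
    bh <- rng$int(1L, maxh)
    bw <- rng$int(1L, maxw)
    if (bh > hw[[1L]] || bw > hw[[2L]]) next
    y0 <- rng$int(1L, hw[[1L]] - bh + 1L)
    x0 <- rng$int(1L, hw[[2L]] - bw + 1L)
    y1 <- y0 + bh - 1L
    x1 <- x0 + bw - 1L
    # candidate plus a 1-pixel moat must avoid existing blob pixels, so
    # 8-connectivity can never join two planted blobs
    my0 <- max(1L, y0 - 1L); my1 <- min(hw[[1L]], y1 + 1L)
    mx0 <- max(1L, x0 - 1L); mx1 <- min(hw[[2L]], x1 + 1L)
    if (any(occupied[my0:my1, mx0:mx1])) next
    occupied[y0:y1, x0:x1] <- TRUE
    placed[[length(placed) + 1L]] <- list(y0 = y0, y1 = y1, x0 = x0, x1 = x1)
  }
  placed
}
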