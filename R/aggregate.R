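# The filter-map-reduce layer. Each aggregator owns: a filter (condition),
# a mapper (node -> contribution), a reducer and a sink. During a run every
# worker accumulates into a PRIVATE shard; shards are merged exactly once
# at completion. Reducer merges are commutative and associative; reducers
# whose output is order-sensitive (lists, tables, stacks) keep their
# elements keyed and canonicalize by natural sort at finalization, which
# makes the finalized artifact independent of scheduling.

#' List the built-in reducer names
#'
#' `count` (elements), `sum_size` (bytes), `list_paths` (sorted path
#' list), `concat_tables` (row-wise CSV concatenation with identical-header
#' check and a `source` provenance column), `stack_images` (keyed 2D
#' slices to a 3D volume, or 3D volumes to a 4D series), `max_project`
#' (elementwise maximum intensity projection to 2D), `describe_images`
#' (per-slice statistics and connected-component object metrics) and
#' `coloc` (pairwise colocalization metrics). Every reducer declares a
#' neutral element; `merge(x, neutral) = x` and merge associativity hold
#' for all of them.
#'
#' @return sorted character vector of reducer names.
#' @export
reducers_builtin <- function() byte_sort(names(reducer_table()))

reducer_table <- function() {
  list(
    count = list(
      element_type = "any",
      neutral = function(p) 0,
      accumulate = function(acc, elem, p) acc + 1,
      merge = function(a, b, p) a + b,
      finalize = function(acc, p) acc),
    sum_size = list(
      element_type = "number",
      neutral = function(p) 0,
      accumulate = function(acc, elem, p) acc + elem,
      merge = function(a, b, p) a + b,
      finalize = function(acc, p) acc),
    list_paths = list(
      element_type = "string",
      neutral = function(p) character(0),
      accumulate = function(acc, elem, p) c(acc, elem),
      merge = function(a, b, p) c(a, b),
      finalize = function(acc, p) byte_sort(acc)),
    concat_tables = list(
      element_type = "table",
      neutral = function(p) list(),
      accumulate = function(acc, elem, p) c(acc, list(elem)),
      merge = function(a, b, p) c(a, b),
      finalize = function(acc, p) finalize_concat_tables(acc)),
    stack_images = list(
      element_type = "image",
      neutral = function(p) list(),
      accumulate = function(acc, elem, p) c(acc, list(elem)),
      merge = function(a, b, p) c(a, b),
      finalize = function(acc, p) {
        stack_images(lapply(acc, function(e) list(e$key, e$img)))
      }),
    max_project = list(
      element_type = "image",
      neutral = function(p) NULL,
      accumulate = function(acc, elem, p) mip_combine(acc, elem$img),
      merge = function(a, b, p) {
        if (is.null(a)) return(b)
        if (is.null(b)) return(a)
        mip_combine(a, b)
      },
      finalize = function(acc, p) {
        if (is.null(acc)) stop("max_project: no images collected",
                               call. = FALSE)
        acc
      }),
    describe_images = list(
      element_type = "image",
      neutral = function(p) list(),
      accumulate = function(acc, elem, p) c(acc, list(elem)),
      merge = function(a, b, p) c(a, b),
      finalize = function(acc, p) finalize_describe(acc)),
    coloc = list(
      element_type = "image",
      neutral = function(p) list(),
      accumulate = function(acc, elem, p) c(acc, list(elem)),
      merge = function(a, b, p) c(a, b),
      finalize = function(acc, p) finalize_coloc(acc, p))
  )
}

default_mapper_for <- function(reducer) {
  switch(reducer,
         count = "node_path",
         sum_size = "file_size",
         list_paths = "node_path",
         concat_tables = "load_table",
         stack_images = ,
         max_project = ,
         describe_images = ,
         coloc = "load_image",
         "node_path")
}

mapper_output_type <- function(mapper) {
  switch(mapper,
         node_path = , node_name = "string",
         file_size = "number",
         load_image = "image",
         load_table = "table",
         "any")
}

# ---- stacking and projection ---------------------------------------------

#' Stack keyed 2D slices into a 3D volume
#'
#' Slices are ordered by natural (numeric-aware) sort of their keys, so
#' `z2` stacks before `z10` regardless of lexicographic order. All slices
#' must share one shape. Passing keyed 3D volumes instead produces a 4D
#' series (time axis first) under the same rules.
#'
#' @param slices list of `list(key, image)` pairs (2-element lists; names
#'   optional).
#' @return array with the stacking axis first: `(z, y, x)` for 2D inputs,
#'   `(t, z, y, x)` for 3D inputs.
#' @export
stack_images <- function(slices) {
  if (length(slices) == 0L) {
    stop("stack_images: cannot build a volume from zero slices",
         call. = FALSE)
  }
  keys <- vapply(slices, function(s) as.character(s[[1L]]), "")
  imgs <- lapply(slices, `[[`, 2L)
  ord <- natural_order(keys)
  keys <- keys[ord]
  imgs <- imgs[ord]
  ref <- dim(imgs[[1L]]) %||% stop("stack_images: elements must be arrays")
  for (i in seq_along(imgs)) {
    if (!identical(dim(imgs[[i]]), ref)) {
      stop("stack_images: slice '", keys[[i]], "' has shape ",
           paste(dim(imgs[[i]]), collapse = "x"), ", expected ",
           paste(ref, collapse = "x"), " (from '", keys[[1L]], "')",
           call. = FALSE)
    }
  }
  out <- array(0, dim = c(length(imgs), ref))
  if (length(ref) == 2L) {
    for (i in seq_along(imgs)) out[i, , ] <- imgs[[i]]
  } else if (length(ref) == 3L) {
    for (i in seq_along(imgs)) out[i, , , ] <- imgs[[i]]
  } else {
    stop("stack_images: elements must be 2D or 3D", call. = FALSE)
  }
  attr(out, "keys") <- keys
  out
}

#' Maximum intensity projection
#'
#' Elementwise maximum across the slice axis (axis 1) of a 3D volume,
#' producing a 2D image.
#'
#' @param volume 3D array `(z, y, x)`.
#' @return 2D matrix `(y, x)`.
#' @export
max_project <- function(volume) {
  stopifnot(length(dim(volume)) == 3L)
  apply(volume, c(2L, 3L), max)
}

# pairwise elementwise max used by the streaming max_project reducer;
# 3D contributions are projected before combining.
mip_combine <- function(acc, img) {
  if (length(dim(img)) == 3L) img <- max_project(img)
  if (is.null(acc)) return(img)
  if (!identical(dim(acc), dim(img))) {
    stop("max_project: image shape ", paste(dim(img), collapse = "x"),
         " does not match accumulated ", paste(dim(acc), collapse = "x"),
         call. = FALSE)
  }
  pmax(acc, img)
}

# ---- per-slice descriptive statistics ------------------------------------

#' Per-slice descriptive statistics of an image volume
#'
#' One row per z-slice: mean, population standard deviation, min,
#' quartiles, max, fraction of nonzero pixels, and object metrics where
#' objects are 8-connected components of the nonzero mask within the slice
#' (no linking across slices). `object_sizes` is a `;`-separated list of
#' component pixel counts in decreasing size. An all-zero slice has
#' `object_count` 0 and fully defined statistics.
#'
#' @param volume 2D matrix (treated as one slice) or 3D `(z, y, x)` array.
#' @return data.frame with one row per slice.
#' @export
describe_images <- function(volume) {
  if (length(dim(volume)) == 2L) {
    volume <- array(volume, dim = c(1L, dim(volume)))
  }
  stopifnot(length(dim(volume)) == 3L)
  rows <- lapply(seq_len(dim(volume)[1L]), function(i) {
    slice_stats(volume[i, , ], i)
  })
  do.call(rbind, rows)
}

slice_stats <- function(slice, index) {
  v <- as.vector(slice)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  sizes <- component_sizes(slice != 0)
  data.frame(
    slice = index,
    mean = mean(v),
    std = sqrt(mean((v - mean(v))^2)),
    min = min(v),
    q25 = q[[1L]],
    median = q[[2L]],
    q75 = q[[3L]],
    max = max(v),
    nonzero_fraction = mean(v != 0),
    object_count = length(sizes),
    object_sizes = paste(sizes, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' 8-connected component labeling of a binary mask
#'
#' Two-pass union-find labeling; pixels touching horizontally, vertically
#' or diagonally belong to one object.
#'
#' @param mask logical matrix.
#' @return integer matrix of labels, 0 for background; labels are numbered
#'   1..n in raster-scan order of first contact.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask)
  nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  nxt <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j]) next
      # previously-scanned 8-neighbours (left column and above in this one)
      neigh <- integer(0)
      if (i > 1L && mask[i - 1L, j]) neigh <- c(neigh, labels[i - 1L, j])
      if (j > 1L) {
        if (mask[i, j - 1L]) neigh <- c(neigh, labels[i, j - 1L])
        if (i > 1L && mask[i - 1L, j - 1L])
          neigh <- c(neigh, labels[i - 1L, j - 1L])
        if (i < nr && mask[i + 1L, j - 1L])
          neigh <- c(neigh, labels[i + 1L, j - 1L])
      }
      if (length(neigh) == 0L) {
        nxt <- nxt + 1L
        parent[[nxt]] <- nxt
        labels[i, j] <- nxt
      } else {
        roots <- unique(vapply(neigh, find, 0L))
        keep <- min(roots)
        labels[i, j] <- keep
        for (r in roots) parent[[r]] <- keep
      }
    }
  }
  if (nxt == 0L) return(labels)
  # flatten and renumber 1..n in order of first appearance
  roots <- vapply(seq_len(nxt), find, 0L)
  pos <- which(labels > 0L)
  flat <- roots[labels[pos]]
  remap <- integer(nxt)
  seen <- unique(flat[order(pos)])
  remap[seen] <- seq_along(seen)
  labels[pos] <- remap[flat]
  labels
}

component_sizes <- function(mask) {
  labels <- label_components(mask)
  if (max(labels) == 0L) return(integer(0))
  sort(tabulate(labels[labels > 0L]), decreasing = TRUE)
}

# ---- colocalization -------------------------------------------------------

#' Pixelwise colocalization metrics between two images
#'
#' Returns Pearson r, Spearman rho (midranks for ties), Manders
#' coefficients M1 = sum(a[b > tb]) / sum(a) and M2 (symmetric), and the
#' fraction of pixels jointly above both thresholds. Correlations are
#' undefined (`NA`) when either image is constant; the Manders
#' coefficients remain defined whenever their denominators are positive.
#'
#' @param image_a,image_b numeric arrays of identical shape.
#' @param threshold_a,threshold_b intensity thresholds (default 0): a
#'   pixel "contains signal" in a channel when strictly above its
#'   threshold.
#' @return named list: `pearson_r`, `spearman_rho`, `manders_m1`,
#'   `manders_m2`, `overlap_fraction`, `n_pixels`; a `note` attribute
#'   explains any undefined metric.
#' @export
coloc <- function(image_a, image_b, threshold_a = 0, threshold_b = 0) {
  if (!identical(dim(image_a), dim(image_b))) {
    stop("coloc: image shapes differ (",
         paste(dim(image_a), collapse = "x"), " vs ",
         paste(dim(image_b), collapse = "x"), ")", call. = FALSE)
  }
  a <- as.vector(image_a)
  b <- as.vector(image_b)
  note <- NULL
  const_a <- stats::sd(a) == 0
  const_b <- stats::sd(b) == 0
  if (const_a || const_b) {
    r <- NA_real_
    rho <- NA_real_
    note <- "correlation undefined: at least one image is constant"
  } else {
    am <- a - mean(a)
    bm <- b - mean(b)
    r <- sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
    ra <- rank(a)
    rb <- rank(b)
    ram <- ra - mean(ra)
    rbm <- rb - mean(rb)
    rho <- sum(ram * rbm) / sqrt(sum(ram^2) * sum(rbm^2))
  }
  sa <- sum(a)
  sb <- sum(b)
  m1 <- if (sa > 0) sum(a[b > threshold_b]) / sa else NA_real_
  m2 <- if (sb > 0) sum(b[a > threshold_a]) / sb else NA_real_
  res <- list(
    pearson_r = r,
    spearman_rho = rho,
    manders_m1 = m1,
    manders_m2 = m2,
    overlap_fraction = mean(a > threshold_a & b > threshold_b),
    n_pixels = length(a)
  )
  if (!is.null(note)) attr(res, "note") <- note
  res
}

finalize_coloc <- function(acc, p) {
  if (length(acc) != 2L) {
    stop("coloc: expected exactly 2 images, aggregator '",
         p$name %||% "?", "' collected ", length(acc), call. = FALSE)
  }
  keys <- vapply(acc, function(e) as.character(e$key), "")
  ord <- natural_order(keys)
  a <- acc[[ord[[1L]]]]
  b <- acc[[ord[[2L]]]]
  m <- coloc(a$img, b$img,
             threshold_a = p$threshold_a %||% 0,
             threshold_b = p$threshold_b %||% 0)
  out <- data.frame(image_a = a$key, image_b = b$key,
                    pearson_r = m$pearson_r, spearman_rho = m$spearman_rho,
                    manders_m1 = m$manders_m1, manders_m2 = m$manders_m2,
                    overlap_fraction = m$overlap_fraction,
                    n_pixels = m$n_pixels, stringsAsFactors = FALSE)
  if (!is.null(attr(m, "note"))) attr(out, "note") <- attr(m, "note")
  out
}

finalize_concat_tables <- function(acc) {
  if (length(acc) == 0L) {
    return(data.frame(source = character(0), stringsAsFactors = FALSE))
  }
  keys <- vapply(acc, function(e) as.character(e$key), "")
  acc <- acc[natural_order(keys)]
  ref <- names(acc[[1L]]$df)
  for (e in acc[-1L]) {
    if (!identical(names(e$df), ref)) {
      stop("concat_tables: header of '", e$source, "' (",
           paste(names(e$df), collapse = ","), ") does not match '",
           acc[[1L]]$source, "' (", paste(ref, collapse = ","), ")",
           call. = FALSE)
    }
  }
  out <- do.call(rbind, lapply(acc, function(e) {
    df <- e$df
    df$source <- e$source
    df
  }))
  rownames(out) <- NULL
  out
}

finalize_describe <- function(acc) {
  if (length(acc) == 0L) {
    return(describe_images(array(0, c(1L, 1L, 1L)))[0L, ])
  }
  keys <- vapply(acc, function(e) as.character(e$key), "")
  acc <- acc[natural_order(keys)]
  out <- list()
  idx <- 0L
  for (e in acc) {
    img <- e$img
    if (length(dim(img)) == 2L) img <- array(img, c(1L, dim(img)))
    for (i in seq_len(dim(img)[1L])) {
      idx <- idx + 1L
      row <- slice_stats(img[i, , ], idx)
      row$source <- e$source %||% e$key
      out[[idx]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- shards ---------------------------------------------------------------

new_shard <- function(owner, reducer, params) {
  sh <- new.env(parent = emptyenv())
  sh$owner <- owner
  sh$partial <- reducer$neutral(params)
  sh$element_count <- 0L
  sh$consumed <- FALSE
  sh
}

shard_add <- function(shard, reducer, elem, params) {
  shard$partial <- reducer$accumulate(shard$partial, elem, params)
  shard$element_count <- shard$element_count + 1L
  invisible(shard)
}

#' Merge worker shards and finalize an aggregate
#'
#' Shard order does not affect the result: merges are commutative and
#' associative, and order-sensitive reducers canonicalize by sort key at
#' finalization. A shard can be consumed once; merging it again is an
#' internal error.
#'
#' @param shards list of shards for one aggregator (possibly empty).
#' @param reducer a reducer entry from `reducer_table()` or its name.
#' @param params reducer parameters (`sort_key`, `threshold_a`,
#'   `threshold_b`, `name`).
#' @return the finalized aggregate value.
#' @export
merge_shards <- function(shards, reducer, params = list()) {
  if (is.character(reducer)) {
    reducer <- reducer_table()[[reducer]] %||%
      stop("unknown reducer '", reducer, "'", call. = FALSE)
  }
  acc <- reducer$neutral(params)
  for (sh in shards) {
    if (isTRUE(sh$consumed)) {
      stop("internal error: shard of worker ", sh$owner,
           " merged twice", call. = FALSE)
    }
    sh$consumed <- TRUE
    acc <- reducer$merge(acc, sh$partial, params)
  }
  reducer$finalize(acc, params)
}

# ---- sinks ----------------------------------------------------------------

#' Write a finalized aggregate to its sink
#'
#' `text_list`: one element per line, sorted, `\n` endings, UTF-8.
#' `csv_table`: RFC-4180 CSV with a header row. `image_file`: uncompressed
#' TIFF (2D or 3D; a 4D series is written as pages in `(t, z)` order).
#' `stdout`: a human-readable one-liner. File writes are atomic (temp file
#' plus rename), so an interrupted run never leaves a partial artifact.
#'
#' @param aggregate finalized value from [merge_shards()].
#' @param sink list with `$kind` and `$destination`.
#' @param base_dir base for relative destinations.
#' @param name aggregator name (used in the stdout format).
#' @return destination path (invisibly), or `NULL` for stdout.
#' @export
write_sink <- function(aggregate, sink, base_dir = getwd(), name = "aggregate") {
  kind <- sink$kind %||% "stdout"
  if (kind == "stdout") {
    cat(format_aggregate(name, aggregate), "\n", sep = "")
    return(invisible(NULL))
  }
  dest <- resolve_path(sink$destination, base_dir)
  if (kind == "text_list") {
    vals <- byte_sort(as.character(aggregate))
    atomic_write(dest, function(tmp) {
      con <- file(tmp, open = "wb")
      on.exit(close(con))
      if (length(vals) > 0L) {
        writeLines(enc2utf8(vals), con, sep = "\n", useBytes = TRUE)
      }
    })
  } else if (kind == "csv_table") {
    stopifnot(is.data.frame(aggregate))
    atomic_write(dest, function(tmp) {
      utils::write.csv(aggregate, tmp, row.names = FALSE, fileEncoding = "UTF-8")
    })
  } else if (kind == "image_file") {
    img <- aggregate
    if (length(dim(img)) == 4L) {
      d <- dim(img)
      img <- array(aperm(img, c(2L, 1L, 3L, 4L)),
                   dim = c(d[[1L]] * d[[2L]], d[[3L]], d[[4L]]))
    }
    atomic_write(dest, function(tmp) write_image(img, tmp),
                 fileext = ".tif")
  } else {
    stop("unknown sink kind '", kind, "'", call. = FALSE)
  }
  invisible(dest)
}

format_aggregate <- function(name, value) {
  if (is.numeric(value) && length(value) == 1L) {
    paste0(name, ": ", format(value, scientific = FALSE))
  } else if (is.character(value)) {
    paste0(name, ": ", length(value), " item",
           if (length(value) == 1L) "" else "s")
  } else if (is.data.frame(value)) {
    paste0(name, ": table with ", nrow(value), " row",
           if (nrow(value) == 1L) "" else "s", ", ",
           ncol(value), " columns")
  } else if (is.array(value)) {
    paste0(name, ": image ", paste(dim(value), collapse = "x"))
  } else {
    paste0(name, ": ", class(value)[[1L]])
  }
}
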