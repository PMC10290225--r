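rt <- recipefs:::reducer_table()
params <- list(name = "t", sort_key = NULL, threshold_a = 0, threshold_b = 0)

test_that("every reducer has a true neutral and an associative merge", {
  probes <- list(
    count = list("a", "b", "c"),
    sum_size = list(3, 10, 29),
    list_paths = list("b", "a", "c"),
    concat_tables = list(
      list(key = "k2", df = data.frame(x = 1), source = "s2"),
      list(key = "k1", df = data.frame(x = 2), source = "s1"),
      list(key = "k3", df = data.frame(x = 3), source = "s3")),
    stack_images = list(
      list(key = "z2", img = matrix(2, 2, 2)),
      list(key = "z10", img = matrix(10, 2, 2)),
      list(key = "z1", img = matrix(1, 2, 2))),
    max_project = list(
      list(key = "a", img = matrix(c(1, 5, 3, 2), 2, 2)),
      list(key = "b", img = matrix(c(4, 0, 2, 9), 2, 2)),
      list(key = "c", img = matrix(0, 2, 2))),
    describe_images = list(
      list(key = "s2", img = matrix(1, 3, 3), source = "s2"),
      list(key = "s1", img = matrix(0, 3, 3), source = "s1"),
      list(key = "s3", img = matrix(2, 3, 3), source = "s3")),
    coloc = list(
      list(key = "c1", img = matrix(1:9 / 9, 3, 3)),
      list(key = "c0", img = matrix(9:1 / 9, 3, 3)))
  )
  for (nm in names(rt)) {
    red <- rt[[nm]]
    elems <- probes[[nm]]
    acc <- red$neutral(params)
    for (e in elems) acc <- red$accumulate(acc, e, params)
    # merge with neutral is identity
    expect_identical(red$merge(acc, red$neutral(params), params), acc,
                     label = paste(nm, "right neutral"))
    expect_identical(red$merge(red$neutral(params), acc, params), acc,
                     label = paste(nm, "left neutral"))
    # associativity over singleton shards
    singles <- lapply(elems, function(e)
      red$accumulate(red$neutral(params), e, params))
    if (length(singles) >= 3L) {
      left <- red$merge(red$merge(singles[[1]], singles[[2]], params),
                        singles[[3]], params)
      right <- red$merge(singles[[1]],
                         red$merge(singles[[2]], singles[[3]], params),
                         params)
      expect_identical(red$finalize(left, params),
                       red$finalize(right, params),
                       label = paste(nm, "associativity"))
    }
  }
})

test_that("shard-order independence: all permutations finalize identically", {
  elems <- list("b/z2.tif", "a/z10.tif", "c/z1.tif")
  for (nm in c("count", "list_paths")) {
    red <- rt[[nm]]
    shards <- lapply(elems, function(e)
      red$accumulate(red$neutral(params), e, params))
    ref <- NULL
    for (perm in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                      c(3, 1, 2), c(3, 2, 1))) {
      acc <- red$neutral(params)
      for (i in perm) acc <- red$merge(acc, shards[[i]], params)
      val <- red$finalize(acc, params)
      if (is.null(ref)) ref <- val else expect_identical(val, ref)
    }
  }
})

test_that("random shard partitions of 200 elements match one big shard", {
  rng <- helper_rng(4242)
  elems <- as.character(vapply(1:200, function(i) rng$int(0L, 10000L), 0L))
  for (nm in c("count", "sum_size", "list_paths")) {
    red <- rt[[nm]]
    conv <- if (nm == "sum_size") as.numeric else identity
    single <- red$neutral(params)
    for (e in elems) single <- red$accumulate(single, conv(e), params)
    want <- red$finalize(single, params)
    for (k in 1:8) {
      shards <- replicate(k, red$neutral(params), simplify = FALSE)
      for (e in elems) {
        w <- rng$int(1L, k)
        shards[[w]] <- red$accumulate(shards[[w]], conv(e), params)
      }
      acc <- red$neutral(params)
      for (sh in shards) acc <- red$merge(acc, sh, params)
      expect_identical(red$finalize(acc, params), want,
                       label = paste(nm, "k =", k))
    }
  }
})

test_that("merge_shards refuses to consume a shard twice", {
  sh <- recipefs:::new_shard(1L, rt$count, params)
  recipefs:::shard_add(sh, rt$count, "x", params)
  expect_equal(merge_shards(list(sh), "count", params), 1)
  expect_error(merge_shards(list(sh), "count", params), "twice")
  expect_equal(merge_shards(list(), "count", params), 0)
  expect_error(merge_shards(list(), "no_such"), "unknown reducer")
})

test_that("stacking uses natural sort and checks shapes", {
  vol <- stack_images(list(list("z1", matrix(1, 2, 2)),
                           list("z10", matrix(10, 2, 2)),
                           list("z2", matrix(2, 2, 2))))
  expect_identical(dim(vol), c(3L, 2L, 2L))
  expect_identical(as.numeric(vol[, 1, 1]), c(1, 2, 10))
  expect_identical(attr(vol, "keys"), c("z1", "z2", "z10"))

  one <- stack_images(list(list("only", matrix(7, 3, 4))))
  expect_identical(dim(one), c(1L, 3L, 4L))
  expect_identical(one[1, , ], matrix(7, 3, 4))

  expect_error(stack_images(list()), "zero slices")
  expect_error(stack_images(list(list("a", matrix(0, 2, 2)),
                                 list("bad", matrix(0, 3, 2)))),
               "bad")
})

test_that("3D volumes stack over time into a 4D series", {
  vols <- lapply(0:3, function(t) array(t, dim = c(2L, 3L, 3L)))
  four <- stack_images(list(list("t2", vols[[3]]), list("t0", vols[[1]]),
                            list("t3", vols[[4]]), list("t1", vols[[2]])))
  expect_identical(dim(four), c(4L, 2L, 3L, 3L))
  for (t in 0:3) expect_true(all(four[t + 1, , , ] == t))
})

test_that("maximum projection equals the brute-force elementwise maximum", {
  expect_identical(
    max_project(stack_images(list(
      list("a", matrix(c(1, 3, 5, 2), 2, 2, byrow = TRUE)),
      list("b", matrix(c(4, 2, 0, 9), 2, 2, byrow = TRUE))))),
    matrix(c(4, 3, 5, 9), 2, 2, byrow = TRUE))

  rng <- helper_rng(7)
  for (case in 1:20) {
    n <- rng$int(2L, 6L)
    slices <- lapply(seq_len(n), function(i)
      matrix(vapply(1:12, function(j) as.numeric(rng$int(0L, 255L)),
                    0), 3, 4))
    keyed <- lapply(seq_len(n), function(i)
      list(sprintf("s%d", i), slices[[i]]))
    got <- max_project(stack_images(keyed))
    want <- Reduce(pmax, slices)   # order-free oracle
    expect_identical(got, want)
  }
})

test_that("per-slice statistics: constants, a hand-counted blob, zeros", {
  const <- describe_images(matrix(42, 4, 4))
  expect_equal(const$mean, 42)
  expect_equal(const$std, 0)
  expect_equal(const$min, 42)
  expect_equal(const$max, 42)
  expect_equal(const$nonzero_fraction, 1)
  expect_equal(const$object_count, 1)

  L <- matrix(0, 5, 6)
  L[2, 2] <- 1; L[3, 2] <- 1; L[3, 3] <- 1      # 3-pixel L-shaped blob
  d <- describe_images(L)
  expect_equal(d$object_count, 1)
  expect_identical(d$object_sizes, "3")
  expect_equal(d$nonzero_fraction, 3 / 30)

  z <- describe_images(matrix(0, 3, 3))
  expect_equal(z$object_count, 0)
  expect_identical(z$object_sizes, "")
  expect_equal(z$std, 0)
})

test_that("labeling matches the flood-fill oracle on random masks", {
  rng <- helper_rng(31)
  for (case in 1:40) {
    nr <- rng$int(3L, 12L)
    nc <- rng$int(3L, 12L)
    mask <- matrix(vapply(seq_len(nr * nc),
                          function(i) rng$unif() < 0.35, TRUE), nr, nc)
    expect_identical(recipefs:::component_sizes(mask),
                     as.integer(oracle_flood_sizes(mask)),
                     label = paste("mask case", case))
  }
  # diagonal-only contact is one object under 8-connectivity
  diag2 <- matrix(FALSE, 4, 4)
  diag2[1, 1] <- TRUE; diag2[2, 2] <- TRUE
  expect_identical(recipefs:::component_sizes(diag2), 2L)
})

test_that("colocalization closed forms hold to 1e-12", {
  a <- generate_image(c(9, 7), "ramp")
  ident <- coloc(a, a)
  expect_equal(ident$pearson_r, 1, tolerance = 1e-12)
  expect_equal(ident$spearman_rho, 1, tolerance = 1e-12)
  expect_equal(ident$manders_m1, sum(a[a > 0]) / sum(a), tolerance = 1e-12)

  b <- max(a) - a
  inv <- coloc(a, b)
  expect_equal(inv$pearson_r, -1, tolerance = 1e-12)
  expect_equal(inv$spearman_rho, -1, tolerance = 1e-12)

  left <- matrix(0, 6, 8); left[, 1:4] <- 3
  right <- matrix(0, 6, 8); right[, 5:8] <- 7
  dis <- coloc(left, right)
  expect_identical(dis$manders_m1, 0)
  expect_identical(dis$manders_m2, 0)
  expect_identical(dis$overlap_fraction, 0)

  expect_error(coloc(matrix(0, 2, 2), matrix(0, 3, 3)), "shapes differ")
})

test_that("coloc is symmetric under argument swap and flags constants", {
  rng <- helper_rng(55)
  for (case in 1:10) {
    a <- matrix(vapply(1:30, function(i) rng$int(0L, 255L), 0L), 5, 6)
    b <- matrix(vapply(1:30, function(i) rng$int(0L, 255L), 0L), 5, 6)
    ab <- coloc(a, b)
    ba <- coloc(b, a)
    expect_equal(ab$pearson_r, ba$pearson_r, tolerance = 1e-12)
    expect_equal(ab$spearman_rho, ba$spearman_rho, tolerance = 1e-12)
    expect_equal(ab$manders_m1, ba$manders_m2, tolerance = 1e-12)
    expect_equal(ab$manders_m2, ba$manders_m1, tolerance = 1e-12)
    expect_identical(coloc(a, a)$pearson_r, 1)
  }
  both <- coloc(matrix(5, 3, 3), matrix(2, 3, 3))
  expect_true(is.na(both$pearson_r))
  expect_true(is.na(both$spearman_rho))
  expect_equal(both$manders_m1, 1)    # denominators positive, tau = 0
  expect_match(attr(both, "note"), "constant")
})

test_that("concat_tables enforces identical headers and adds provenance", {
  good <- recipefs:::finalize_concat_tables(list(
    list(key = "b", df = data.frame(x = 3:4, y = 5:6), source = "b.csv"),
    list(key = "a", df = data.frame(x = 1:2, y = 8:9), source = "a.csv")))
  expect_identical(names(good), c("x", "y", "source"))
  expect_identical(good$source, c("a.csv", "a.csv", "b.csv", "b.csv"))
  expect_identical(good$x, c(1:2, 3:4))

  expect_error(recipefs:::finalize_concat_tables(list(
    list(key = "a", df = data.frame(x = 1), source = "a.csv"),
    list(key = "b", df = data.frame(x = 1, z = 2), source = "b.csv"))),
    "a\\.csv.*b\\.csv|b\\.csv.*a\\.csv")
})

test_that("sinks write canonical bytes and survive a round-trip", {
  d <- tempfile(); dir.create(d)
  p <- write_sink(c("b", "a", "c"),
                  list(kind = "text_list", destination = "l.txt"),
                  base_dir = d)
  expect_identical(readBin(p, "raw", 100), charToRaw("a\nb\nc\n"))

  tab <- describe_images(generate_image(c(3, 8, 8), "blobs",
                                        n_blobs = 2, seed = 9))
  p2 <- write_sink(tab, list(kind = "csv_table", destination = "t.csv"),
                   base_dir = d)
  back <- utils::read.csv(p2)
  expect_equal(back$mean, tab$mean, tolerance = 1e-12)
  expect_identical(back$object_count, tab$object_count)
  expect_identical(back$object_sizes,
                   ifelse(tab$object_sizes == "", NA, tab$object_sizes))

  vol <- stack_images(list(list("z1", matrix(3, 4, 4)),
                           list("z2", matrix(9, 4, 4))))
  p3 <- write_sink(vol, list(kind = "image_file", destination = "v.tif"),
                   base_dir = d)
  expect_true(all(read_image(p3) == vol))
})

test_that("an interrupted sink write leaves no partial file behind", {
  d <- tempfile(); dir.create(d)
  dest <- file.path(d, "out.txt")
  expect_error(recipefs:::atomic_write(dest, function(tmp) {
    writeLines("partial", tmp)
    stop("disk gone")
  }), "disk gone")
  expect_false(file.exists(dest))
  expect_length(list.files(d, all.files = TRUE, no.. = TRUE), 0)
})
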