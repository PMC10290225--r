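# One oracle check per shipped gallery recipe. Each check receives the
# output of gallery_run() — the run result plus the fixture ground truth —
# and returns TRUE, or a character description of what disagreed. The
# checks only consult the manifest/ground truth (never the engine's own
# bookkeeping), so they are usable both from testthat and from the
# acceptance script.

gallery_checks <- function() {
  ok <- TRUE
  chk <- function(cond, msg) if (isTRUE(cond)) TRUE else msg
  files_of <- function(m) m[m$kind == "file", , drop = FALSE]

  list(
    "01_count_files.toml" = function(out) {
      f <- files_of(out$truth)
      chk(out$result$aggregates$file_count == nrow(f), "file count mismatch")
    },
    "02_total_bytes.toml" = function(out) {
      f <- files_of(out$truth)
      chk(out$result$aggregates$total_bytes == sum(f$size),
          "byte total mismatch")
    },
    "03_count_and_sizes.toml" = function(out) {
      f <- files_of(out$truth)
      chk(out$result$aggregates$file_count == nrow(f) &&
            out$result$aggregates$total_bytes == sum(f$size),
          "count-and-sizes mismatch")
    },
    "04_list_all_files.toml" = function(out) {
      f <- files_of(out$truth)
      got <- readLines(file.path(out$workspace, "out", "all_files.txt"))
      chk(identical(got, sort(f$path, method = "radix")),
          "listed paths differ from manifest")
    },
    "05_list_images.toml" = function(out) {
      f <- files_of(out$truth)
      want <- sort(f$path[f$type %in% c("png2d", "tiff3d")], method = "radix")
      chk(identical(out$result$aggregates$images, want),
          "image list mismatch")
    },
    "06_count_dirs.toml" = function(out) {
      chk(out$result$aggregates$dir_count ==
            sum(out$truth$kind == "directory"), "dir count mismatch")
    },
    "07_count_csvs.toml" = function(out) {
      f <- files_of(out$truth)
      chk(out$result$aggregates$csv_count == sum(f$type == "csv"),
          "csv count mismatch")
    },
    "08_batch_list_tifs.toml" = function(out) {
      f <- files_of(out$truth)
      want <- sort(f$path[grepl("\\.tif$", f$path)], method = "radix")
      got <- readLines(file.path(out$workspace, "out", "tif_batch.txt"))
      chk(identical(got, want), "tif batch list mismatch")
    },
    "09_count_large.toml" = function(out) {
      f <- files_of(out$truth)
      chk(out$result$aggregates$large_files == sum(f$size >= 256),
          "large-file count mismatch")
    },
    "10_count_hidden.toml" = function(out) {
      chk(out$result$aggregates$hidden_files ==
            sum(out$truth$violation == "hidden"), "hidden count mismatch")
    },
    "11_count_top_level.toml" = function(out) {
      f <- files_of(out$truth)
      chk(out$result$aggregates$top_level_files ==
            sum(f$depth == 1L), "top-level count mismatch")
    },
    "12_validate_ascii_lowercase.toml" = function(out) {
      f <- files_of(out$truth)
      bad <- sum(!grepl("^[a-z0-9_. ]+$", basename(f$path)))
      chk(out$result$failure_count == bad &&
            out$result$status == "validation_failures",
          "lowercase-violation count mismatch")
    },
    "13_validate_contract.toml" = function(out) {
      chk(out$result$failure_count == sum(out$truth$violation != "none"),
          "contract failure count != planted violations")
    },
    "14_validate_csv_schema.toml" = function(out) {
      chk(out$result$failure_count ==
            sum(out$truth$violation == "csv_schema"),
          "csv schema failure count mismatch")
    },
    "15_validate_image_dims.toml" = function(out) {
      chk(out$result$failure_count ==
            sum(out$truth$violation == "wrong_dims"),
          "image dims failure count mismatch")
    },
    "16_warn_on_violation.toml" = function(out) {
      warns <- out$result$journal$detail == "layout contract violated"
      chk(out$result$failure_count == 0L &&
            out$result$status == "ok" &&
            sum(warns) == sum(out$truth$violation != "none"),
          "counteraction warnings != planted violations")
    },
    "17_collect_failures.toml" = function(out) {
      f <- files_of(out$truth)
      bad <- f$path[startsWith(basename(f$path), ".") |
                      !grepl("^[a-z0-9_]+\\.[a-z0-9]+$", basename(f$path))]
      chk(identical(out$result$lists$violations,
                    sort(bad, method = "radix")),
          "collected violators mismatch")
    },
    "18_level_scoped.toml" = function(out) {
      m <- out$truth
      chk(identical(out$result$lists$top,
                    sort(m$path[m$depth == 1L], method = "radix")) &&
            identical(out$result$lists$deeper,
                      sort(m$path[m$depth > 1L], method = "radix")),
          "level-1 rule did not beat the any rule")
    },
    "19_media_by_any_mode.toml" = function(out) {
      f <- files_of(out$truth)
      want <- sort(f$path[f$type %in% c("csv", "png2d", "tiff3d")],
                   method = "radix")
      chk(identical(out$result$lists$media, want),
          "any-mode selection mismatch")
    },
    "20_shared_definitions.toml" = function(out) {
      f <- files_of(out$truth)
      want <- sort(f$path[f$type %in% c("png2d", "tiff3d")], method = "radix")
      chk(identical(out$result$lists$imgs, want), "alias selection mismatch")
    },
    "21_nested_composites.toml" = function(out) {
      f <- files_of(out$truth)
      want <- sort(f$path[grepl("\\.(png|tif)$", f$path)], method = "radix")
      chk(identical(out$result$lists$pics, want),
          "nested composite selection mismatch")
    },
    "22_integer_names.toml" = function(out) {
      chk(identical(out$result$lists$plates,
                    sort(out$truth$integer_plates, method = "radix")),
          "integer-name selection mismatch")
    },
    "23_copy_pngs.toml" = function(out) {
      f <- files_of(out$truth)
      pngs <- basename(f$path[f$type == "png2d"])
      got <- list.files(file.path(out$workspace, "out_png"))
      chk(identical(sort(got, method = "radix"),
                    sort(pngs, method = "radix")) &&
            sum(out$result$journal$effect_kind == "copy") == length(pngs),
          "copied png set mismatch")
    },
    "24_flatten_tifs.toml" = function(out) {
      want <- sort(gsub("/", "_", out$truth$tifs), method = "radix")
      got <- sort(list.files(file.path(out$workspace, "flat")),
                  method = "radix")
      chk(identical(got, want), "flattened names mismatch")
    },
    "25_move_txt.toml" = function(out) {
      moved <- sort(list.files(file.path(out$workspace, "moved_txt")),
                    method = "radix")
      want <- sort(basename(out$truth$txts), method = "radix")
      left <- list.files(out$root, pattern = "\\.txt$", recursive = TRUE)
      chk(identical(moved, want) && length(left) == 0L,
          "move_to left sources or missed files")
    },
    "26_normalize_names.toml" = function(out) {
      now <- list.files(out$root, all.files = TRUE, no.. = TRUE)
      chk("my_data.txt" %in% now && "upper_case.txt" %in% now &&
            !("My Data.txt" %in% now) &&
            sum(out$result$journal$effect_kind == "rename") == 2L,
          "rename normalization mismatch")
    },
    "27_quarantine_tmp.toml" = function(out) {
      q <- paste0(out$root, ".quarantine")
      qfiles <- sort(list.files(q, recursive = TRUE, all.files = TRUE),
                     method = "radix")
      left <- list.files(out$root, pattern = "\\.tmp$", recursive = TRUE,
                         all.files = TRUE)
      chk(identical(qfiles, sort(out$truth$junk, method = "radix")) &&
            length(left) == 0L,
          "quarantine did not mirror the removed files")
    },
    "28_destructive_cleanup.toml" = function(out) {
      # without --allow-destructive the recipe flag alone must NOT delete
      q <- paste0(out$root, ".quarantine")
      left <- list.files(out$root, pattern = "\\.tmp$", recursive = TRUE,
                         all.files = TRUE)
      chk(length(left) == 0L && dir.exists(q),
          "recipe flag alone must quarantine, not delete")
    },
    "29_log_csvs.toml" = function(out) {
      f <- files_of(out$truth)
      want <- sort(f$path[f$type == "csv"], method = "radix")
      log <- file.path(out$workspace, "out", "csv_log.txt")
      if (length(want) == 0L) {
        return(chk(!file.exists(log), "log written with nothing to log"))
      }
      got <- sort(readLines(log), method = "radix")
      chk(identical(got, want), "csv log content mismatch")
    },
    "30_backup_files.toml" = function(out) {
      f <- files_of(out$truth)
      got <- sort(list.files(file.path(out$workspace, "backup")),
                  method = "radix")
      chk(identical(got, sort(basename(f$path), method = "radix")),
          "backup set mismatch")
    },
    "31_quit_first_csv.toml" = function(out) {
      nodes <- walk_tree(out$root, "topdown")
      rels <- vapply(nodes, `[[`, "", "rel")
      first_csv <- which(grepl("\\.csv$", rels) &
                           vapply(nodes, function(n) n$kind == "file", TRUE))
      if (length(first_csv) == 0L) {
        return(chk(!out$result$quit, "quit fired without any csv"))
      }
      chk(out$result$quit &&
            max(out$result$journal$walk_index) == first_csv[[1L]] &&
            identical(out$result$lists$found, rels[first_csv[[1L]]]),
          "early exit fired at the wrong node")
    },
    "32_quit_on_violation.toml" = function(out) {
      chk(out$result$status == "aborted" && out$result$quit,
          "quit_on_fail did not abort")
    },
    "33_bottomup_audit.toml" = function(out) {
      j <- out$result$journal
      idx <- stats::setNames(j$walk_index[j$effect_kind == "list_add"],
                             j$path[j$effect_kind == "list_add"])
      m <- out$truth
      ok <- TRUE
      for (d in m$path[m$kind == "directory"]) {
        kids <- names(idx)[startsWith(names(idx), paste0(d, "/"))]
        if (length(kids) > 0L && any(idx[kids] > idx[[d]])) ok <- FALSE
      }
      chk(ok, "bottom-up order violated (child after parent)")
    },
    "34_stack_slices.toml" = function(out) {
      vol <- out$result$aggregates$zstack
      sv <- out$truth$slice_values
      want <- unname(sv[c("z1", "z2", "z10")])   # natural order
      ondisk <- read_image(file.path(out$workspace, "out", "stack.tif"))
      chk(identical(dim(vol), c(3L, 6L, 5L)) &&
            identical(as.numeric(vol[, 1L, 1L]), as.numeric(want)) &&
            identical(dim(ondisk), dim(vol)) &&
            all(ondisk == vol),
          "z-stack order or content mismatch")
    },
    "35_max_projection.toml" = function(out) {
      mip <- out$result$aggregates$mip
      want <- max(out$truth$slice_values)
      chk(all(mip == want) && identical(dim(mip), c(6L, 5L)),
          "projection differs from slice maximum")
    },
    "36_describe_blobs.toml" = function(out) {
      tab <- utils::read.csv(file.path(out$workspace, "out",
                                       "blob_stats.csv"))
      want_counts <- unname(out$truth$blob_counts[c("b1", "b2", "b3")])
      want_sizes <- vapply(c("b1", "b2", "b3"), function(nm) {
        paste(sort(out$truth$blobs[[nm]]$size, decreasing = TRUE),
              collapse = ";")
      }, "")
      chk(identical(tab$object_count, as.integer(want_counts)) &&
            identical(tab$object_sizes, unname(want_sizes)),
          "blob metrics differ from generator bookkeeping")
    },
    "37_coloc_channels.toml" = function(out) {
      tab <- out$result$aggregates$channel_coloc
      sum_a <- sum(out$truth$ch0)
      peak <- max(out$truth$ch0)
      m1_want <- (sum_a - peak) / sum_a   # b > 0 except at a's maximum
      chk(abs(tab$pearson_r + 1) < 1e-12 &&
            abs(tab$spearman_rho + 1) < 1e-12 &&
            abs(tab$manders_m1 - m1_want) < 1e-12,
          "channel colocalization metrics mismatch")
    },
    "38_stack_timeseries.toml" = function(out) {
      vol <- out$result$aggregates$timeseries
      ok <- identical(dim(vol), c(4L, 2L, 4L, 4L))
      for (t in 0:3) {
        ok <- ok && all(vol[t + 1L, , , ] == out$truth$vols[[paste0("t", t)]])
      }
      chk(ok, "time series blocks differ from source volumes")
    },
    "39_project_volumes.toml" = function(out) {
      want <- Reduce(pmax, lapply(out$truth$vols, function(v)
        apply(v, c(2L, 3L), max)))
      chk(all(out$result$aggregates$series_mip == want),
          "volume projection differs from brute-force maximum")
    },
    "40_concat_measurements.toml" = function(out) {
      tab <- utils::read.csv(file.path(out$workspace, "out", "all_rows.csv"))
      chk(nrow(tab) == out$truth$total_rows &&
            "source" %in% names(tab) &&
            length(unique(tab$source)) == length(out$truth$rows),
          "concatenated table rows or provenance mismatch")
    },
    "41_validate_tables.toml" = function(out) {
      chk(out$result$status == "ok" && out$result$failure_count == 0L,
          "well-formed tables flagged as invalid")
    },
    "42_regex_select.toml" = function(out) {
      f <- out$truth[out$truth$kind == "file", ]
      want <- sort(f$path[f$type %in% c("png2d", "tiff3d")], method = "radix")
      got <- readLines(file.path(out$workspace, "out", "media.txt"))
      chk(identical(got, want), "regex selection mismatch")
    }
  )
}

# run one recipe and apply its oracle check; returns TRUE or a message
check_gallery_recipe <- function(name, seed = 1L, ...) {
  checks <- gallery_checks()
  if (is.null(checks[[name]])) return(paste("no check defined for", name))
  out <- gallery_run(name, seed = seed, ...)
  checks[[name]](out)
}
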