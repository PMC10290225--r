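#' Natural (numeric-aware) ordering of strings
#'
#' Orders strings so that embedded runs of digits compare as integers:
#' `"z2"` sorts before `"z10"`. Non-digit segments compare bytewise
#' (C locale); ties on the numeric key fall back to plain bytewise order
#' so the ordering is total and platform-independent.
#'
#' @param x character vector.
#' @return integer permutation, as [order()].
#' @examples
#' c("z1", "z10", "z2")[natural_order(c("z1", "z10", "z2"))]
#' @export
natural_order <- function(x) {
  if (length(x) == 0L) return(integer(0))
  # split each string into alternating non-digit / digit runs
  pieces <- regmatches(x, gregexpr("[0-9]+|[^0-9]+", x))
  nmax <- max(lengths(pieces), 1L)
  keys <- vector("list", nmax)
  for (i in seq_len(nmax)) {
    seg <- vapply(pieces, function(p) if (length(p) >= i) p[[i]] else "", "")
    isnum <- grepl("^[0-9]+$", seg) & nzchar(seg)
    num <- rep(NA_real_, length(seg))
    num[isnum] <- as.numeric(seg[isnum])
    # numbers sort before text within a segment slot; empty (exhausted) first
    rank3 <- ifelse(!nzchar(seg), 0L, ifelse(isnum, 1L, 2L))
    txt <- ifelse(isnum, "", seg)
    num[!isnum] <- 0
    keys[[3L * i - 2L]] <- rank3
    keys[[3L * i - 1L]] <- num
    keys[[3L * i]] <- txt
  }
  keys <- keys[!vapply(keys, is.null, TRUE)]
  keys <- c(keys, list(x))  # final tie-break: bytewise on the full string
  do.call(order, c(keys, list(method = "radix")))
}

#' @rdname natural_order
#' @export
natural_sort <- function(x) x[natural_order(x)]

# Bytewise (C locale) sort: the "left to right" sibling order of traversal.
byte_sort <- function(x) sort(x, method = "radix")

path_join <- function(...) {
  parts <- c(...)
  parts <- parts[nzchar(parts)]
  do.call(file.path, as.list(parts))
}

# relative path of `path` under `root`, with "/" separators
rel_path <- function(path, root) {
  p <- normalizePath(path, winslash = "/", mustWork = FALSE)
  r <- normalizePath(root, winslash = "/", mustWork = FALSE)
  if (identical(p, r)) return(".")
  sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", r), "/?"), "", p)
}

file_ext_lower <- function(path) {
  name <- basename(path)
  m <- regmatches(name, regexpr("\\.[^.]*$", name))
  if (length(m) == 0L) "" else tolower(m)
}

strip_ext <- function(name) sub("\\.[^.]*$", "", name)

#' Content hash of a directory tree
#'
#' MD5 digest summarising every file's relative path and content plus every
#' directory's relative path. Two trees hash equal iff they contain the same
#' entries with the same bytes. Used by tests for mutation-safety and
#' quarantine-reversibility checks.
#'
#' @param root directory to hash.
#' @return single hex string.
#' @export
tree_hash <- function(root) {
  stopifnot(dir.exists(root))
  files <- list.files(root, recursive = TRUE, all.files = TRUE,
                      full.names = FALSE, no.. = TRUE, include.dirs = TRUE)
  files <- byte_sort(files)
  lines <- character(0)
  for (f in files) {
    fp <- file.path(root, f)
    if (dir.exists(fp)) {
      lines <- c(lines, paste0("D ", f))
    } else {
      lines <- c(lines, paste0("F ", f, " ", unname(tools::md5sum(fp))))
    }
  }
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  unname(tools::md5sum(tmp))
}

# Atomic text/binary write: write to a temp file in the destination
# directory, then rename. An interrupted write never leaves a partial file.
atomic_write <- function(dest, writer, fileext = "") {
  dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(pattern = ".rfs_tmp_", tmpdir = dirname(dest),
                  fileext = fileext)
  ok <- FALSE
  tryCatch({
    writer(tmp)
    ok <- TRUE
  }, finally = if (!ok && file.exists(tmp)) unlink(tmp))
  if (!file.rename(tmp, dest)) {
    unlink(tmp)
    stop("cannot write to sink destination: ", dest, call. = FALSE)
  }
  invisible(dest)
}

# Collision-avoiding destination: append _1, _2, ... before the extension.
# Returns the first free path; order-dependent by design (documented).
uncollide <- function(dest) {
  if (!file.exists(dest) && !dir.exists(dest)) return(dest)
  dir <- dirname(dest)
  name <- basename(dest)
  ext <- ""
  m <- regexpr("\\.[^.]*$", name)
  if (m > 1L) {
    ext <- substring(name, m)
    name <- substring(name, 1L, m - 1L)
  }
  i <- 1L
  repeat {
    cand <- file.path(dir, paste0(name, "_", i, ext))
    if (!file.exists(cand) && !dir.exists(cand)) return(cand)
    i <- i + 1L
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
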