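#' Read a grayscale image (TIFF or PNG)
#'
#' Images are handled as 8-bit grayscale with intensities on the 0..255
#' scale. A 2D image is a `y x x` matrix; a multi-page TIFF becomes a 3D
#' array with the slice axis first (`z x y x x`), so `img[i, , ]` is the
#' i-th page.
#'
#' @param path image file; format chosen by extension (.tif/.tiff/.png).
#' @return numeric matrix (2D) or 3D array, values in 0..255.
#' @export
read_image <- function(path) {
  ext <- file_ext_lower(path)
  if (ext %in% c(".tif", ".tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, drop_channels)
    if (length(pages) == 1L) return(round(pages[[1L]] * 255))
    vol <- array(0, dim = c(length(pages), dim(pages[[1L]])))
    for (i in seq_along(pages)) vol[i, , ] <- pages[[i]]
    return(round(vol * 255))
  }
  if (ext == ".png") {
    return(round(drop_channels(png::readPNG(path)) * 255))
  }
  stop("unsupported image format: ", path, call. = FALSE)
}

# Collapse RGB(A) planes to one grayscale channel (first channel).
drop_channels <- function(img) {
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

#' Write a grayscale image (TIFF or PNG)
#'
#' Inverse of [read_image()]: accepts a matrix or a 3D array with the slice
#' axis first. TIFF output is uncompressed 8-bit so identical pixel data
#' always yields identical bytes.
#'
#' @param img numeric matrix or `z x y x x` array, values 0..255.
#' @param path destination; `.tif`/`.tiff` (2D or 3D) or `.png` (2D only).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  ext <- file_ext_lower(path)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  scaled <- pmin(pmax(img, 0), 255) / 255
  if (ext %in% c(".tif", ".tiff")) {
    if (length(dim(scaled)) == 3L) {
      pages <- lapply(seq_len(dim(scaled)[1L]), function(i) scaled[i, , ])
    } else {
      pages <- list(as.matrix(scaled))
    }
    tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  } else if (ext == ".png") {
    if (length(dim(scaled)) == 3L)
      stop("PNG supports 2D images only", call. = FALSE)
    png::writePNG(as.matrix(scaled), path)
  } else {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  invisible(path)
}

image_ndims <- function(img) length(dim(img))

is_image_path <- function(path) {
  file_ext_lower(path) %in% c(".tif", ".tiff", ".png")
}
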