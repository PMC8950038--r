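# Core raster types and reading/writing in standard formats.
#
# Conventions fixed once and used everywhere downstream (post-processing,
# metrics): matrices are indexed (row, col), row-major, 1-based. Integer
# images carry their bit depth ("uint8"/"uint16"); float images live on
# [0, 1] and are stored as 32-bit TIFF (stored at 2^-32 quantisation).

#' Construct a grayscale image
#'
#' A `gray_image` is a numeric matrix of non-negative intensities with a
#' recorded storage type: `"uint8"`, `"uint16"` (raw camera counts) or
#' `"float"` (normalised intensities on \[0, 1\]).
#'
#' @param pixels Numeric matrix, all values finite and non-negative.
#' @param dtype One of `"uint8"`, `"uint16"`, `"float"`.
#' @return A `gray_image` object (matrix with class and `dtype` attribute).
#' @export
gray_image <- function(pixels, dtype = c("uint16", "uint8", "float")) {
  dtype <- match.arg(dtype)
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    err_shape("`pixels` must be a matrix with at least one row and column")
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("intensities must be finite and non-negative")
  if (dtype == "uint8"  && any(pixels > 255))   stop("uint8 intensities exceed 255")
  if (dtype == "uint16" && any(pixels > 65535)) stop("uint16 intensities exceed 65535")
  if (dtype == "float"  && any(pixels > 1))     stop("float intensities must lie in [0, 1]")
  if (dtype != "float") pixels[] <- round(pixels)
  structure(pixels, dtype = dtype, class = c("gray_image", class(matrix())))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, %s, range [%g, %g]>\n",
              nrow(x), ncol(x), attr(x, "dtype"), min(x), max(x)))
  invisible(x)
}

#' Bit depth of a grayscale image
#' @param image A [gray_image()].
#' @return 8, 16, or the string `"float"`.
#' @export
dtype_bits <- function(image) {
  switch(attr(image, "dtype"), uint8 = 8L, uint16 = 16L, "float")
}

#' Construct an instance label map
#'
#' Non-negative integer matrix; 0 is background, each positive label is one
#' nucleus. Labels need not be consecutive.
#'
#' @param labels Matrix of non-negative integers.
#' @return An `instance_mask` object.
#' @export
instance_mask <- function(labels) {
  if (!is.matrix(labels)) err_shape("`labels` must be a matrix")
  if (any(!is.finite(labels)) || any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  structure(labels, class = c("instance_mask", class(matrix())))
}

#' Number of distinct positive labels in a mask
#' @param mask An [instance_mask()].
#' @return Integer count of instances.
#' @export
n_instances <- function(mask) length(setdiff(unique(as.vector(mask)), 0L))

#' @export
print.instance_mask <- function(x, ...) {
  cat(sprintf("<instance_mask %d x %d, %d instances>\n",
              nrow(x), ncol(x), n_instances(x)))
  invisible(x)
}

#' Construct a three-class semantic label map
#'
#' Per-pixel categorical label: 0 = background, 1 = nucleus interior,
#' 2 = nucleus boundary.
#'
#' @param classes Matrix over \{0, 1, 2\}.
#' @return A `three_class_label` object.
#' @export
three_class_label <- function(classes) {
  if (!is.matrix(classes)) err_shape("`classes` must be a matrix")
  if (!all(classes %in% 0:2)) stop("classes must be 0 (background), 1 (interior) or 2 (boundary)")
  storage.mode(classes) <- "integer"
  structure(classes, class = c("three_class_label", class(matrix())))
}

#' Construct a class-probability map
#'
#' H x W x 3 array of per-pixel probabilities over (background, interior,
#' boundary); each pixel's triple sums to 1.
#'
#' @param probs Numeric array with `dim = c(H, W, 3)`.
#' @return A `prob_map` object.
#' @export
prob_map <- function(probs) {
  if (!is.array(probs) || length(dim(probs)) != 3L || dim(probs)[3] != 3L)
    err_shape("`probs` must be an H x W x 3 array")
  if (any(probs < -1e-8)) stop("probabilities must be non-negative")
  s <- probs[, , 1] + probs[, , 2] + probs[, , 3]
  if (max(abs(s - 1)) > 1e-5) stop("per-pixel probabilities must sum to 1 (tolerance 1e-5)")
  structure(probs, class = c("prob_map", class(array(0, c(1, 1, 1)))))
}

prob_channel <- function(prob, which = c("background", "interior", "boundary")) {
  which <- match.arg(which)
  prob[, , match(which, c("background", "interior", "boundary"))]
}

# ---------------------------------------------------------------------------
# Reading

image_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) "tiff" else if (ext == "png") "png"
  else err_unsupported(sprintf("unsupported image format '.%s'", ext))
}

# Collapse a H x W x C array to a matrix, insisting the channels agree.
collapse_channels <- function(a, path) {
  if (is.matrix(a)) return(a)
  if (length(dim(a)) == 3L) {
    nc <- dim(a)[3]
    if (nc == 1L) return(a[, , 1])
    # drop a constant saturated alpha channel (2- or 4-channel gray/RGBA)
    if (nc %in% c(2L, 4L) && all(a[, , nc] == max(a[, , nc]))) {
      a <- a[, , -nc, drop = FALSE]
      nc <- dim(a)[3]
      if (nc == 1L) return(a[, , 1])
    }
    for (k in seq_len(nc - 1L))
      if (any(a[, , k] != a[, , k + 1L]))
        err_unsupported(sprintf("'%s' is multi-channel with distinct channels; expected grayscale", path))
    return(a[, , 1])
  }
  err_unsupported(sprintf("'%s' has unsupported dimensionality", path))
}

#' Read a grayscale image
#'
#' Reads a single-channel 8/16-bit or 32-bit TIFF, or an 8/16-bit PNG.
#' Multi-channel files whose channels are identical are collapsed; truly
#' colored input is rejected. Intensities are never rescaled: integer files
#' come back as raw counts, float files as stored.
#'
#' @param path Path to a `.tif`/`.tiff`/`.png` file.
#' @return A [gray_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) err_not_found(sprintf("image file '%s' does not exist", path))
  fmt <- image_format(path)
  if (fmt == "tiff") {
    info <- tiff::readTIFF(path, payload = FALSE)
    if (is.data.frame(info)) info <- info[1, , drop = FALSE]
    bps <- info$bits.per.sample
    fmtf <- if (!is.null(info$sample.format) && identical(info$sample.format, "float")) TRUE else bps >= 32
    if (fmtf) {
      px <- collapse_channels(tiff::readTIFF(path), path)
      return(gray_image(px, "float"))
    }
    px <- collapse_channels(tiff::readTIFF(path, as.is = TRUE), path)
    gray_image(px * 1.0, if (bps <= 8) "uint8" else "uint16")
  } else {
    px <- png::readPNG(path, info = TRUE)
    bits <- attr(px, "info")$bit.depth
    px <- collapse_channels(px, path)
    gray_image(round(px * (2^bits - 1)), if (bits <= 8) "uint8" else "uint16")
  }
}

#' Write a grayscale image
#'
#' Lossless counterpart of [read_image()]: `uint8`/`uint16` images are
#' written at their native bit depth (TIFF or 8-bit PNG), `float` images as
#' 32-bit TIFF (stored at 2^-32 quantisation).
#'
#' @param image A [gray_image()].
#' @param path Destination path; parent directory must exist.
#' @export
write_image <- function(image, path) {
  if (!dir.exists(dirname(path))) err_io(sprintf("directory '%s' does not exist", dirname(path)))
  fmt <- image_format(path)
  dt <- attr(image, "dtype")
  px <- unclass(image); attributes(px) <- list(dim = dim(px))
  if (fmt == "tiff") {
    if (dt == "float") tiff::writeTIFF(px, path, bits.per.sample = 32L)
    else {
      b <- if (dt == "uint8") 8L else 16L
      tiff::writeTIFF(px / (2^b - 1), path, bits.per.sample = b)
    }
  } else {
    if (dt != "uint8")
      err_unsupported("PNG output supports only uint8 images; use TIFF for 16-bit or float data")
    png::writePNG(px / 255, path)
  }
  invisible(path)
}

#' Read an instance label map
#'
#' Accepts integer-typed single-channel TIFF/PNG label maps. Label maps
#' written by [write_label_map()] with labels above 65535 use a two-page
#' 16-bit TIFF (high word, low word) and are reassembled transparently.
#' Files with non-integral pixel values are rejected.
#'
#' @param path Path to the label file.
#' @return An [instance_mask()].
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) err_not_found(sprintf("label file '%s' does not exist", path))
  fmt <- image_format(path)
  if (fmt == "tiff") {
    info <- tiff::readTIFF(path, payload = FALSE, all = TRUE)
    if (!is.data.frame(info)) info <- as.data.frame(info)
    bps <- info$bits.per.sample[1]
    sfmt <- info$sample.format[1]
    if (identical(sfmt, "float") || (length(bps) && bps >= 32)) {
      px <- tiff::readTIFF(path)
      px <- collapse_channels(px, path)
      if (any(px != round(px)))
        err_unsupported(sprintf("'%s' contains non-integral (float) pixel values", path))
      return(instance_mask(px))
    }
    pg <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
    if (length(pg) == 2L) {
      hi <- collapse_channels(pg[[1]], path); lo <- collapse_channels(pg[[2]], path)
      return(instance_mask(hi * 65536 + lo))
    }
    instance_mask(collapse_channels(pg[[1]], path))
  } else {
    px <- png::readPNG(path, info = TRUE)
    bits <- attr(px, "info")$bit.depth
    px <- collapse_channels(px, path)
    instance_mask(round(px * (2^bits - 1)))
  }
}

#' Write an instance label map
#'
#' Labels are stored losslessly as 16-bit TIFF when the maximum label fits
#' below 65536, else as a two-page 16-bit TIFF holding the high and low
#' 16-bit words of each label.
#'
#' @param mask An [instance_mask()].
#' @param path Destination `.tif`/`.tiff` path; parent directory must exist.
#' @export
write_label_map <- function(mask, path) {
  if (!dir.exists(dirname(path))) err_io(sprintf("directory '%s' does not exist", dirname(path)))
  if (image_format(path) != "tiff") err_unsupported("label maps are written as TIFF")
  m <- unclass(mask); attributes(m) <- list(dim = dim(m)); m <- m * 1.0
  if (max(m) < 65536) {
    tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  } else {
    hi <- floor(m / 65536); lo <- m - hi * 65536
    tiff::writeTIFF(list(hi / 65535, lo / 65535), path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Read a three-class probability map
#'
#' Reads the 3-page 32-bit TIFF layout written by [write_prob_map()]
#' (page order: background, interior, boundary).
#'
#' @param path Path to the probability TIFF.
#' @return A [prob_map()].
#' @export
read_prob_map <- function(path) {
  if (!file.exists(path)) err_not_found(sprintf("probability file '%s' does not exist", path))
  pg <- tiff::readTIFF(path, all = TRUE)
  if (length(pg) != 3L) err_unsupported("probability maps must have exactly 3 pages")
  a <- array(0, c(dim(pg[[1]]), 3L))
  for (k in 1:3) a[, , k] <- pg[[k]]
  # float32 storage wobble: renormalise within read tolerance
  s <- a[, , 1] + a[, , 2] + a[, , 3]
  for (k in 1:3) a[, , k] <- a[, , k] / s
  prob_map(a)
}

#' Write a three-class probability map
#'
#' @param prob A [prob_map()].
#' @param path Destination `.tif`/`.tiff` path.
#' @export
write_prob_map <- function(prob, path) {
  if (!dir.exists(dirname(path))) err_io(sprintf("directory '%s' does not exist", dirname(path)))
  pg <- lapply(1:3, function(k) {
    m <- prob[, , k]; attributes(m) <- list(dim = dim(m)); pmin(pmax(m, 0), 1)
  })
  tiff::writeTIFF(pg, path, bits.per.sample = 32L)
  invisible(path)
}
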