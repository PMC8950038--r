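# Pre-processing: percentile grayscale normalisation, conversion of
# instance ground truth to the three-class semantic target, inverse-
# frequency class weights, and 90-degree rotation / flip augmentation.

#' Pre-processing configuration
#'
#' @param norm_low_percentile,norm_high_percentile Percentiles mapped to 0
#'   and 1 by [normalize_grayscale()]; the defaults (0.1, 99.9) are robust
#'   to the hot-pixel outliers typical of fluorescence data.
#' @param boundary_width Width in pixels of the boundary class drawn on the
#'   inner rim of each instance (chessboard distance to the instance
#'   complement).
#' @param augment_rotations Subset of `c(0, 90, 180, 270)` degrees.
#'   Restricted to multiples of 90 so categorical labels never need
#'   interpolation.
#' @param augment_flips Subset of `c("horizontal", "vertical")`; the
#'   identity (no flip) is always in the pool.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(norm_low_percentile = 0.1,
                              norm_high_percentile = 99.9,
                              boundary_width = 2L,
                              augment_rotations = c(0, 90, 180, 270),
                              augment_flips = c("horizontal", "vertical")) {
  stopifnot(norm_low_percentile >= 0, norm_high_percentile <= 100,
            norm_low_percentile < norm_high_percentile, boundary_width >= 1)
  if (!all(augment_rotations %in% c(0, 90, 180, 270)))
    stop("rotations must be multiples of 90 degrees")
  if (length(augment_flips) && !all(augment_flips %in% c("horizontal", "vertical")))
    stop("flips must be 'horizontal' and/or 'vertical'")
  structure(list(norm_low_percentile = norm_low_percentile,
                 norm_high_percentile = norm_high_percentile,
                 boundary_width = as.integer(boundary_width),
                 augment_rotations = sort(unique(augment_rotations)),
                 augment_flips = unique(augment_flips)),
            class = "preprocess_config")
}

#' Percentile grayscale normalisation
#'
#' Linearly maps the configured low/high intensity percentiles to 0 and 1
#' and clips to \[0, 1\], making contours comparable across exposures while
#' ignoring hot-pixel outliers. A constant image maps to all zeros.
#'
#' @param image A [gray_image()].
#' @param config A [preprocess_config()].
#' @return A float [gray_image()] on \[0, 1\].
#' @export
normalize_grayscale <- function(image, config = preprocess_config()) {
  px <- unclass(image); attributes(px) <- list(dim = dim(px))
  q <- stats::quantile(px, c(config$norm_low_percentile,
                             config$norm_high_percentile) / 100, names = FALSE)
  if (q[2] - q[1] <= .Machine$double.eps * max(1, abs(q[2])))
    return(gray_image(matrix(0, nrow(px), ncol(px)), "float"))
  out <- (px - q[1]) / (q[2] - q[1])
  gray_image(pmin(pmax(out, 0), 1), "float")
}

#' Convert an instance mask to a three-class semantic label
#'
#' Per instance, pixels within `boundary_width` (chessboard distance, i.e.
#' box-kernel morphology) of the instance's complement become the boundary
#' class; the remaining instance pixels are interior; label 0 stays
#' background. An instance so small that erosion would empty it keeps its
#' innermost pixel (maximum distance to the complement; ties broken by
#' smallest row, then column) as interior, so every instance retains at
#' least one interior pixel and remains seedable.
#'
#' @param mask An [instance_mask()].
#' @param boundary_width Boundary rim width in pixels (>= 1).
#' @return A [three_class_label()].
#' @export
instance_to_three_class <- function(mask, boundary_width = 2L) {
  stopifnot(boundary_width >= 1)
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0L, H, W)
  labs <- setdiff(sort(unique(as.vector(mask))), 0L)
  brush <- EBImage::makeBrush(2L * as.integer(boundary_width) + 1L, "box")
  m <- unclass(mask); attributes(m) <- list(dim = dim(m))
  for (lb in labs) {
    sel <- which(m == lb, arr.ind = TRUE)
    r0 <- max(1L, min(sel[, 1]) - 1L); r1 <- min(H, max(sel[, 1]) + 1L)
    c0 <- max(1L, min(sel[, 2]) - 1L); c1 <- min(W, max(sel[, 2]) + 1L)
    crop <- (m[r0:r1, c0:c1, drop = FALSE] == lb) * 1
    # pad so instances touching the image edge are not eroded from outside
    bw <- as.integer(boundary_width)
    padded <- matrix(0, nrow(crop) + 2L * bw, ncol(crop) + 2L * bw)
    padded[bw + seq_len(nrow(crop)), bw + seq_len(ncol(crop))] <- crop
    # image-edge pixels count as instance support, not complement
    if (r0 == 1L) padded[seq_len(bw), ] <- padded[rep(bw + 1L, bw), ]
    if (r1 == H)  padded[nrow(padded) - seq_len(bw) + 1L, ] <- padded[rep(nrow(padded) - bw, bw), ]
    if (c0 == 1L) padded[, seq_len(bw)] <- padded[, rep(bw + 1L, bw)]
    if (c1 == W)  padded[, ncol(padded) - seq_len(bw) + 1L] <- padded[, rep(ncol(padded) - bw, bw)]
    interior <- EBImage::erode(padded, brush)[bw + seq_len(nrow(crop)),
                                              bw + seq_len(ncol(crop)), drop = FALSE]
    cls <- matrix(0L, nrow(crop), ncol(crop))
    cls[crop > 0] <- 2L
    cls[interior > 0 & crop > 0] <- 1L
    if (!any(cls == 1L)) {
      d <- EBImage::distmap(padded)[bw + seq_len(nrow(crop)),
                                    bw + seq_len(ncol(crop)), drop = FALSE]
      d[crop == 0] <- -Inf
      best <- which(d == max(d), arr.ind = TRUE)
      best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, , drop = FALSE]
      cls[best] <- 1L
    }
    block <- out[r0:r1, c0:c1, drop = FALSE]
    block[cls > 0L] <- cls[cls > 0L]
    out[r0:r1, c0:c1] <- block
  }
  three_class_label(out)
}

#' Inverse-frequency class weights
#'
#' Weight for class c is `total_pixels / (3 * pixels_of_c)` accumulated
#' over the whole collection, so balanced data yields (1, 1, 1) and rare
#' classes (typically boundary) are up-weighted in the loss.
#'
#' @param labels A [three_class_label()] or list of them.
#' @return A `class_weights` list with `w_background`, `w_interior`,
#'   `w_boundary`.
#' @export
compute_class_weights <- function(labels) {
  if (inherits(labels, "three_class_label")) labels <- list(labels)
  counts <- c(0, 0, 0)
  for (lb in labels) {
    t <- tabulate(as.vector(lb) + 1L, nbins = 3L)
    counts <- counts + t
  }
  if (any(counts == 0))
    err_missing_class(sprintf("class(es) %s absent from the label collection",
                              paste(c("background", "interior", "boundary")[counts == 0],
                                    collapse = ", ")))
  w <- sum(counts) / (3 * counts)
  class_weights(w[1], w[2], w[3])
}

#' Construct class weights
#' @param w_background,w_interior,w_boundary Positive reals.
#' @return A `class_weights` list.
#' @export
class_weights <- function(w_background = 1, w_interior = 1, w_boundary = 1) {
  stopifnot(w_background > 0, w_interior > 0, w_boundary > 0)
  structure(list(w_background = w_background, w_interior = w_interior,
                 w_boundary = w_boundary), class = "class_weights")
}

rot90_mat <- function(m, k) {
  k <- k %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE][, , drop = FALSE]
  m
}

flip_mat <- function(m, which) {
  switch(which,
         none = m,
         horizontal = m[, ncol(m):1, drop = FALSE],   # mirror left-right
         vertical = m[nrow(m):1, , drop = FALSE])     # mirror top-bottom
}

#' Random rotation/flip augmentation of an image-label pair
#'
#' Samples one transform uniformly from the configured rotation x flip
#' group and applies it identically to image and label. Deterministic
#' given `rng_seed`.
#'
#' @param image A [gray_image()].
#' @param label A [three_class_label()] of the same shape.
#' @param config A [preprocess_config()].
#' @param rng_seed Integer seed.
#' @return List with transformed `image` and `label` plus the sampled
#'   `rotation` and `flip`.
#' @export
augment_pair <- function(image, label, config = preprocess_config(), rng_seed = 1L) {
  if (!all(dim(image) == dim(label))) err_shape("image and label shapes differ")
  rots <- config$augment_rotations
  flips <- c("none", config$augment_flips)
  with_seed(rng_seed, {
    rot <- rots[sample.int(length(rots), 1L)]
    flp <- flips[sample.int(length(flips), 1L)]
    im <- flip_mat(rot90_mat(unclass(image), rot / 90), flp)
    lb <- flip_mat(rot90_mat(unclass(label), rot / 90), flp)
    attributes(im) <- list(dim = dim(im))
    attributes(lb) <- list(dim = dim(lb))
    list(image = gray_image(im, attr(image, "dtype")),
         label = three_class_label(lb),
         rotation = rot, flip = flp)
  })
}
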