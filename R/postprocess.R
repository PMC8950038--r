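# Post-processing: converting three-class probability maps to instance
# labels. The primary decoder is interior expansion -- synchronized seeded
# growth up to the boundary-probability ridge -- with marker-based
# watershed and plain threshold labeling as ablation alternatives.

#' Post-processing configuration
#'
#' @param seed_threshold Interior-probability threshold for seeding;
#'   strictly-greater comparison (default 0.5).
#' @param connectivity Pixel connectivity for seeding and growth, 4 or 8
#'   (default 8: avoids spurious fragmentation of diagonal nuclei).
#' @param max_iterations Cap on expansion iterations; default (`NULL`)
#'   uses the image diagonal.
#' @param method One of `"interior_expansion"`, `"watershed"`,
#'   `"threshold"`.
#' @param epsilon Plateau tolerance for the non-decreasing boundary
#'   probability rule.
#' @return A `postprocess_config` list.
#' @export
postprocess_config <- function(seed_threshold = 0.5, connectivity = 8L,
                               max_iterations = NULL,
                               method = c("interior_expansion", "watershed",
                                          "threshold"),
                               epsilon = 1e-6) {
  method <- match.arg(method)
  stopifnot(seed_threshold > 0, seed_threshold < 1, connectivity %in% c(4L, 8L))
  structure(list(seed_threshold = seed_threshold,
                 connectivity = as.integer(connectivity),
                 max_iterations = max_iterations, method = method,
                 epsilon = epsilon),
            class = "postprocess_config")
}

#' Label connected components of a binary mask
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return An [instance_mask()] with one label per component.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  instance_mask(.cpp_label_components(m, as.integer(connectivity)))
}

#' Seed nuclei from the interior probability
#'
#' Pixels whose interior probability strictly exceeds the threshold are
#' binarised and connected components become one seed label each.
#'
#' @param prob A [prob_map()].
#' @param config A [postprocess_config()].
#' @return An [instance_mask()] of seed labels.
#' @export
seed_from_interior <- function(prob, config = postprocess_config()) {
  p_int <- prob_channel(prob, "interior")
  label_components(p_int > config$seed_threshold, config$connectivity)
}

#' Grow interior seeds to the boundary-probability ridge
#'
#' Synchronized seeded growth: at each iteration every seed's frontier may
#' claim unassigned neighbour pixels where background is not the dominant
#' class and the boundary probability has not dropped (non-decreasing
#' within `epsilon`, or the neighbour is interior-dominant). A pixel
#' claimable by two different labels in the same iteration is contested
#' and stays unassigned forever, which keeps touching nuclei separated by
#' a one-pixel-wide gap. Growth along a direction stops once the
#' candidate's boundary probability falls below the current pixel's (past
#' the ridge crest); crest pixels claimed in that last step are discarded
#' from the label. The output is the union of the original seed pixels and
#' the retained expansion pixels.
#'
#' @param prob A [prob_map()].
#' @param seeds An [instance_mask()] of the same shape (typically from
#'   [seed_from_interior()]).
#' @param config A [postprocess_config()].
#' @return An [instance_mask()] of pairwise-disjoint instances.
#' @export
interior_expansion <- function(prob, seeds = NULL, config = postprocess_config()) {
  if (is.null(seeds)) seeds <- seed_from_interior(prob, config)
  if (any(dim(prob)[1:2] != dim(seeds)))
    err_shape("probability map and seeds differ in shape")
  maxit <- config$max_iterations
  if (is.null(maxit)) maxit <- ceiling(sqrt(nrow(seeds)^2 + ncol(seeds)^2))
  s <- unclass(seeds); attributes(s) <- list(dim = dim(s))
  storage.mode(s) <- "integer"
  out <- .cpp_interior_expansion(prob[, , 1], prob[, , 2], prob[, , 3], s,
                                 as.integer(config$connectivity),
                                 config$epsilon, as.integer(maxit))
  instance_mask(out)
}

#' Marker-based watershed post-processing
#'
#' Markers are the interior seeds; the elevation surface is
#' `p_boundary - p_interior`; flooding is restricted to pixels where
#' background is not the dominant class.
#'
#' @param prob A [prob_map()].
#' @param config A [postprocess_config()].
#' @return An [instance_mask()].
#' @export
watershed_postprocess <- function(prob, config = postprocess_config()) {
  seeds <- seed_from_interior(prob, config)
  elev <- prob_channel(prob, "boundary") - prob_channel(prob, "interior")
  region <- prob_channel(prob, "background") < pmax(prob_channel(prob, "interior"),
                                                    prob_channel(prob, "boundary"))
  region <- region | unclass(seeds) > 0L
  s <- unclass(seeds); attributes(s) <- list(dim = dim(s)); storage.mode(s) <- "integer"
  instance_mask(.cpp_marker_watershed(elev, s, region, as.integer(config$connectivity)))
}

#' Threshold labeling of the probability map
#'
#' Per-pixel argmax; connected components of the interior class become
#' instances. Excluding argmax-boundary pixels is what separates clumped
#' nuclei in this baseline.
#'
#' @param prob A [prob_map()].
#' @param config A [postprocess_config()].
#' @return An [instance_mask()].
#' @export
threshold_labeling <- function(prob, config = postprocess_config()) {
  p_bg <- prob_channel(prob, "background")
  p_in <- prob_channel(prob, "interior")
  p_bd <- prob_channel(prob, "boundary")
  interior <- p_in > p_bg & p_in > p_bd
  label_components(interior, config$connectivity)
}

#' Convert a probability map to instances with the configured method
#'
#' @param prob A [prob_map()].
#' @param config A [postprocess_config()]; `config$method` selects the
#'   decoder.
#' @return An [instance_mask()].
#' @export
postprocess_probmap <- function(prob, config = postprocess_config()) {
  switch(config$method,
         interior_expansion = interior_expansion(prob, config = config),
         watershed = watershed_postprocess(prob, config),
         threshold = threshold_labeling(prob, config))
}

#' Ideal probability map from a ground-truth mask
#'
#' One-hot probability field built from the three-class rendering of an
#' instance mask; useful for isolating post-processing behaviour from
#' network accuracy.
#'
#' @param truth An [instance_mask()].
#' @param boundary_width Boundary rim width passed to
#'   [instance_to_three_class()].
#' @return A [prob_map()].
#' @export
ideal_prob_map <- function(truth, boundary_width = 2L) {
  cls <- instance_to_three_class(truth, boundary_width)
  a <- array(0, c(dim(cls), 3L))
  for (k in 0:2) a[, , k + 1L] <- (unclass(cls) == k) * 1
  prob_map(a)
}
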