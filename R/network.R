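# Network builders: the cascade attention-gated encoder-decoder (ASW-Net),
# its gate-free sibling (SW-Net) and a plain 3-scale U-Net baseline. All
# map a normalised grayscale image to per-pixel probabilities over
# background / interior / boundary.
#
# ASW-Net wiring (filters f = base_filters, geometric doubling per scale):
#   C0 = block(x; 1 -> f)                 full resolution
#   C1 = block(pool C0; f -> 2f)          1/2
#   C2 = block(pool C1; 2f -> 4f)         1/4
#   U1 = upconv(C2; 4f -> 2f)             1/2   gate1 skips C1
#   C3 = block([U1, gate1(C1, U1)]; -> 2f)
#   C4 = block(pool C3; 2f -> 4f)         1/4
#   U2 = upconv(C4; 4f -> 2f)             1/2   gate2 skips C3
#   C5 = block([U2, gate2(C3, U2)]; -> 2f)
#   U3 = upconv(C5; 2f -> f)              full  gate3 skips C0
#   C6 = block([U3, gate3(C0, U3)]; -> f)
#   logits = conv1x1([C6, x]; f+1 -> 3)   original input re-entered here
# Two down-samplings, one up; one more down, two more ups: the 'W'. The
# raw input joins only the final block, not the first up-sampling path.
# SW-Net replaces each gate with the plain skip. The middle skip re-enters
# the last features produced at the 1/2 scale (C3); Figure-level wiring
# choices like this one are centralised here so alternatives are one-line
# swaps.

#' Network configuration
#'
#' @param base_filters Channel count at full resolution; deeper scales use
#'   2x and 4x (default 16).
#' @param kernel_size Convolution kernel size in the encoder/decoder
#'   blocks (odd, default 3).
#' @param use_attention Attach attention gates to the up-sampling skips
#'   (`TRUE` = ASW-Net, `FALSE` = SW-Net).
#' @param use_batchnorm Insert per-channel normalisation after each
#'   convolution (default `TRUE`).
#' @param padding `"zero"` (default) or `"wrap"` (circular; useful for
#'   shift-covariance checks).
#' @param rng_seed Seed for He-style weight initialisation.
#' @return A `network_config` list.
#' @export
network_config <- function(base_filters = 16L, kernel_size = 3L,
                           use_attention = TRUE, use_batchnorm = TRUE,
                           padding = c("zero", "wrap"), rng_seed = 1L) {
  padding <- match.arg(padding)
  stopifnot(base_filters >= 1, kernel_size %% 2 == 1)
  structure(list(base_filters = as.integer(base_filters),
                 kernel_size = as.integer(kernel_size),
                 use_attention = isTRUE(use_attention),
                 use_batchnorm = isTRUE(use_batchnorm),
                 padding = padding, n_classes = 3L,
                 depth_downsamples = 3L,
                 rng_seed = as.integer(rng_seed)),
            class = "network_config")
}

he_init <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))), c(k, k, cin, cout))
}

init_block <- function(params, name, k, cin, cout, bn) {
  params[[paste0(name, ".conv1.w")]] <- he_init(k, cin, cout)
  params[[paste0(name, ".conv1.b")]] <- numeric(cout)
  params[[paste0(name, ".conv2.w")]] <- he_init(k, cout, cout)
  params[[paste0(name, ".conv2.b")]] <- numeric(cout)
  if (bn) {
    for (i in 1:2) {
      params[[paste0(name, ".bn", i, ".g")]] <- rep(1, cout)
      params[[paste0(name, ".bn", i, ".b")]] <- numeric(cout)
    }
  }
  params
}

init_upconv <- function(params, name, cin, cout) {
  params[[paste0(name, ".w")]] <- he_init(2L, cin, cout)
  params[[paste0(name, ".b")]] <- numeric(cout)
  params
}

init_gate <- function(params, name, c_skip, c_gate) {
  f <- max(c_skip %/% 2L, 1L)
  params[[paste0(name, ".wx.w")]] <- he_init(1L, c_skip, f)
  params[[paste0(name, ".wg.w")]] <- he_init(1L, c_gate, f)
  params[[paste0(name, ".wg.b")]] <- numeric(f)
  params[[paste0(name, ".psi.w")]] <- he_init(1L, f, 1L)
  params[[paste0(name, ".psi.b")]] <- numeric(1L)
  params
}

new_model <- function(variant, config, params) {
  structure(list(variant = variant, config = config, params = params,
                 parameter_count = sum(vapply(params, length, 1L))),
            class = "aswnet_model")
}

#' @export
print.aswnet_model <- function(x, ...) {
  cat(sprintf("<%s model: base_filters=%d, kernel=%d, %s, %d parameters>\n",
              toupper(x$variant), x$config$base_filters, x$config$kernel_size,
              if (x$config$use_attention) "attention gates" else "plain skips",
              x$parameter_count))
  invisible(x)
}

#' Build the attention-gated cascade network (ASW-Net)
#'
#' Three down-sampling and three up-sampling stages arranged as a 'W'
#' (down, down, up, down, up, up) with an attention gate on every
#' up-sampling skip; the raw input is concatenated back in just before the
#' 1x1 classification convolution, but deliberately not on the first
#' up-sampling path. Deterministic given `config$rng_seed`.
#'
#' @param config A [network_config()] (with `use_attention = TRUE`).
#' @return An `aswnet_model` handle with fields `variant`, `config`,
#'   `params`, `parameter_count`.
#' @export
build_asw_net <- function(config = network_config()) {
  config$use_attention <- TRUE
  build_w_variant("asw", config)
}

#' Build SW-Net (the same cascade without attention gates)
#' @param config A [network_config()]; `use_attention` is forced off.
#' @return An `aswnet_model` handle.
#' @export
build_sw_net <- function(config = network_config()) {
  config$use_attention <- FALSE
  build_w_variant("sw", config)
}

build_w_variant <- function(variant, config) {
  f <- config$base_filters; k <- config$kernel_size; bn <- config$use_batchnorm
  with_seed(config$rng_seed, {
    p <- list()
    p <- init_block(p, "c0", k, 1L, f, bn)
    p <- init_block(p, "c1", k, f, 2L * f, bn)
    p <- init_block(p, "c2", k, 2L * f, 4L * f, bn)
    p <- init_upconv(p, "u1", 4L * f, 2L * f)
    p <- init_block(p, "c3", k, 4L * f, 2L * f, bn)
    p <- init_block(p, "c4", k, 2L * f, 4L * f, bn)
    p <- init_upconv(p, "u2", 4L * f, 2L * f)
    p <- init_block(p, "c5", k, 4L * f, 2L * f, bn)
    p <- init_upconv(p, "u3", 2L * f, f)
    p <- init_block(p, "c6", k, 2L * f, f, bn)
    if (config$use_attention) {
      p <- init_gate(p, "g1", 2L * f, 2L * f)
      p <- init_gate(p, "g2", 2L * f, 2L * f)
      p <- init_gate(p, "g3", f, f)
    }
    p[["head.w"]] <- he_init(1L, f + 1L, 3L)
    p[["head.b"]] <- numeric(3L)
    new_model(variant, config, p)
  })
}

#' Build a plain 3-scale U-Net baseline
#'
#' Standard symmetric encoder-decoder with plain skip concatenations and
#' the same 3-class softmax head.
#'
#' @param config A [network_config()]; attention is ignored.
#' @return An `aswnet_model` handle.
#' @export
build_u_net <- function(config = network_config()) {
  f <- config$base_filters; k <- config$kernel_size; bn <- config$use_batchnorm
  config$use_attention <- FALSE
  with_seed(config$rng_seed, {
    p <- list()
    p <- init_block(p, "e0", k, 1L, f, bn)
    p <- init_block(p, "e1", k, f, 2L * f, bn)
    p <- init_block(p, "e2", k, 2L * f, 4L * f, bn)
    p <- init_block(p, "bott", k, 4L * f, 8L * f, bn)
    p <- init_upconv(p, "u2", 8L * f, 4L * f)
    p <- init_block(p, "d2", k, 8L * f, 4L * f, bn)
    p <- init_upconv(p, "u1", 4L * f, 2L * f)
    p <- init_block(p, "d1", k, 4L * f, 2L * f, bn)
    p <- init_upconv(p, "u0", 2L * f, f)
    p <- init_block(p, "d0", k, 2L * f, f, bn)
    p[["head.w"]] <- he_init(1L, f, 3L)
    p[["head.b"]] <- numeric(3L)
    new_model("unet", config, p)
  })
}

tp_block <- function(tp, xid, name, cfg) {
  pad <- cfg$padding
  h <- tp_conv(tp, xid, paste0(name, ".conv1.w"), paste0(name, ".conv1.b"), pad)
  if (cfg$use_batchnorm) h <- tp_bn(tp, h, paste0(name, ".bn1.g"), paste0(name, ".bn1.b"))
  h <- tp_relu(tp, h)
  h <- tp_conv(tp, h, paste0(name, ".conv2.w"), paste0(name, ".conv2.b"), pad)
  if (cfg$use_batchnorm) h <- tp_bn(tp, h, paste0(name, ".bn2.g"), paste0(name, ".bn2.b"))
  tp_relu(tp, h)
}

# Additive attention gate on the tape. skip and gating share spatial dims
# here (the gating signal is the upsampled decoder feature). Returns the
# gated skip and the coefficient-map node id.
tp_attention <- function(tp, skip_id, gate_id, name, cfg) {
  # 1x1 projections; wx has no bias (absorbed by wg's)
  f <- dim(tp$params[[paste0(name, ".wx.w")]])[4]
  if (is.null(tp$params[[paste0(name, ".wx.b0")]]))
    tp$params[[paste0(name, ".wx.b0")]] <- numeric(f)   # constant zero, not trained
  ax <- tp_conv(tp, skip_id, paste0(name, ".wx.w"), paste0(name, ".wx.b0"), cfg$padding)
  ag <- tp_conv(tp, gate_id, paste0(name, ".wg.w"), paste0(name, ".wg.b"), cfg$padding)
  s <- tp_relu(tp, tp_add(tp, ax, ag))
  coef <- tp_sigmoid(tp, tp_conv(tp, s, paste0(name, ".psi.w"), paste0(name, ".psi.b"),
                                 cfg$padding))
  list(gated = tp_mul_coef(tp, skip_id, coef), coef = coef)
}

# Forward pass building the full tape. Returns the tape plus node ids of
# the logits, probabilities, per-block features and gate coefficients.
net_forward <- function(model, x, training = FALSE) {
  d <- dim(x)
  if (is.matrix(x)) x <- array(x, c(d, 1L))
  if (any(dim(x)[1:2] %% 8L != 0L))
    err_shape("input spatial dims must be divisible by 8 (three 2x down-samplings)")
  cfg <- model$config
  tp <- tape_new(model$params, training = training)
  xin <- tp_input(tp, x)
  ids <- list(); coefs <- list()
  if (model$variant %in% c("asw", "sw")) {
    c0 <- tp_block(tp, xin, "c0", cfg)
    c1 <- tp_block(tp, tp_maxpool(tp, c0), "c1", cfg)
    c2 <- tp_block(tp, tp_maxpool(tp, c1), "c2", cfg)
    u1 <- tp_upconv(tp, c2, "u1.w", "u1.b")
    if (cfg$use_attention) {
      g1 <- tp_attention(tp, c1, u1, "g1", cfg); s1 <- g1$gated; coefs$g1 <- g1$coef
    } else s1 <- c1
    c3 <- tp_block(tp, tp_concat(tp, u1, s1), "c3", cfg)
    c4 <- tp_block(tp, tp_maxpool(tp, c3), "c4", cfg)
    u2 <- tp_upconv(tp, c4, "u2.w", "u2.b")
    if (cfg$use_attention) {
      g2 <- tp_attention(tp, c3, u2, "g2", cfg); s2 <- g2$gated; coefs$g2 <- g2$coef
    } else s2 <- c3
    c5 <- tp_block(tp, tp_concat(tp, u2, s2), "c5", cfg)
    u3 <- tp_upconv(tp, c5, "u3.w", "u3.b")
    if (cfg$use_attention) {
      g3 <- tp_attention(tp, c0, u3, "g3", cfg); s3 <- g3$gated; coefs$g3 <- g3$coef
    } else s3 <- c0
    c6 <- tp_block(tp, tp_concat(tp, u3, s3), "c6", cfg)
    logits <- tp_conv(tp, tp_concat(tp, c6, xin), "head.w", "head.b", cfg$padding)
    ids <- list(c0 = c0, c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, c6 = c6)
  } else {
    e0 <- tp_block(tp, xin, "e0", cfg)
    e1 <- tp_block(tp, tp_maxpool(tp, e0), "e1", cfg)
    e2 <- tp_block(tp, tp_maxpool(tp, e1), "e2", cfg)
    bo <- tp_block(tp, tp_maxpool(tp, e2), "bott", cfg)
    d2 <- tp_block(tp, tp_concat(tp, tp_upconv(tp, bo, "u2.w", "u2.b"), e2), "d2", cfg)
    d1 <- tp_block(tp, tp_concat(tp, tp_upconv(tp, d2, "u1.w", "u1.b"), e1), "d1", cfg)
    d0 <- tp_block(tp, tp_concat(tp, tp_upconv(tp, d1, "u0.w", "u0.b"), e0), "d0", cfg)
    logits <- tp_conv(tp, d0, "head.w", "head.b", cfg$padding)
    ids <- list(e0 = e0, e1 = e1, e2 = e2, bott = bo, d2 = d2, d1 = d1, d0 = d0)
  }
  list(tape = tp, logits = logits, blocks = ids, coefs = coefs)
}

softmax3 <- function(logits) {
  m <- pmax(logits[, , 1], logits[, , 2], logits[, , 3])
  e <- exp(logits - as.vector(m))
  s <- e[, , 1] + e[, , 2] + e[, , 3]
  e / as.vector(s)
}

#' Forward logits for a (divisible-by-8) input
#'
#' Low-level forward pass without padding; mainly useful for architecture
#' diagnostics. Use [predict_probmap()] for arbitrary image sizes.
#'
#' @param model An `aswnet_model`.
#' @param x Numeric matrix (normalised image).
#' @return H x W x 3 array of pre-softmax logits.
#' @export
forward_logits <- function(model, x) {
  fw <- net_forward(model, unclass(x), training = FALSE)
  tp_value(fw$tape, fw$logits)
}

#' Predict a three-class probability map
#'
#' Normalised image in, per-pixel class probabilities out. Images whose
#' dimensions are not divisible by 8 are reflect-padded to the next
#' multiple and the logits cropped back, so output shape always equals
#' input shape.
#'
#' @param model An `aswnet_model`.
#' @param image A float [gray_image()] (see [normalize_grayscale()]) or a
#'   numeric matrix.
#' @return A [prob_map()].
#' @export
predict_probmap <- function(model, image) {
  x <- unclass(image); attributes(x) <- list(dim = dim(x))
  H <- nrow(x); W <- ncol(x)
  Hp <- 8L * ((H + 7L) %/% 8L); Wp <- 8L * ((W + 7L) %/% 8L)
  if (Hp != H || Wp != W) {
    ri <- c(seq_len(H), rev(seq_len(H))[seq_len(Hp - H)])
    ci <- c(seq_len(W), rev(seq_len(W))[seq_len(Wp - W)])
    x <- x[ri, ci, drop = FALSE]
  }
  fw <- net_forward(model, x, training = FALSE)
  logits <- tp_value(fw$tape, fw$logits)[seq_len(H), seq_len(W), , drop = FALSE]
  prob_map(softmax3(logits))
}

#' Apply an additive attention gate to a feature field
#'
#' Projects the skip features and the gating signal to a common
#' intermediate width with 1x1 convolutions, sums, applies ReLU, projects
#' to a single channel, and squashes with a sigmoid; the resulting
#' coefficient map in (0, 1) multiplies the skip features elementwise. A
#' gating signal at a coarser resolution is upsampled (nearest neighbour)
#' to the skip resolution first.
#'
#' @param skip H x W x Cs array of skip features.
#' @param gating h x w x Cg array with `h <= H`, `w <= W` (integer factor).
#' @param params Optional named list `wx` (1 x 1 x Cs x F), `wg`
#'   (1 x 1 x Cg x F), `wg_b` (F), `psi` (1 x 1 x F x 1), `psi_b` (1). If
#'   `NULL`, He-initialised from `rng_seed` with zero biases (so an
#'   untrained gate is centred on coefficient 0.5).
#' @param rng_seed Seed for the default initialisation.
#' @return List with `gated` (H x W x Cs) and `coefficients` (H x W) in
#'   (0, 1).
#' @export
attention_gate <- function(skip, gating, params = NULL, rng_seed = 1L) {
  if (length(dim(skip)) != 3L || length(dim(gating)) != 3L)
    err_shape("skip and gating must be H x W x C arrays")
  ds <- dim(skip); dg <- dim(gating)
  if (ds[1] %% dg[1] != 0L || ds[2] %% dg[2] != 0L || ds[1] < dg[1])
    err_shape("gating spatial dims must divide the skip dims")
  fac <- ds[1] %/% dg[1]
  if (ds[2] %/% dg[2] != fac) err_shape("anisotropic gating/skip resampling not supported")
  if (is.null(params)) {
    f <- max(ds[3] %/% 2L, 1L)
    params <- with_seed(rng_seed, list(wx = he_init(1L, ds[3], f),
                                       wg = he_init(1L, dg[3], f), wg_b = numeric(f),
                                       psi = he_init(1L, f, 1L), psi_b = numeric(1L)))
  }
  if (dim(params$wg)[3] != dg[3] || dim(params$wx)[3] != ds[3])
    err_shape("gate parameter channel counts do not match the inputs")
  g <- gating
  if (fac > 1L) g <- gating[rep(seq_len(dg[1]), each = fac),
                            rep(seq_len(dg[2]), each = fac), , drop = FALSE]
  f <- dim(params$wx)[4]
  proj <- function(x, w, b) {
    xm <- matrix(x, prod(dim(x)[1:2]), dim(x)[3])
    array(sweep(xm %*% matrix(w, dim(w)[3], dim(w)[4]), 2L, b, `+`),
          c(dim(x)[1:2], dim(w)[4]))
  }
  s <- proj(skip, params$wx, numeric(f)) + proj(g, params$wg, params$wg_b)
  s <- s * (s > 0)
  coef <- 1 / (1 + exp(-(proj(s, params$psi, params$psi_b)[, , 1])))
  list(gated = skip * as.vector(coef), coefficients = coef)
}
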