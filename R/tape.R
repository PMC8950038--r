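# A minimal reverse-mode autodiff tape over H x W x C arrays, sufficient
# for the segmentation networks in this package: 2-D convolution (same
# padding, zero or wrap), 2x2 max pooling, 2x2-stride-2 transposed
# convolution, per-channel normalisation, ReLU/sigmoid, channel concat,
# elementwise add and broadcast multiply. Convolutions are evaluated as
# im2col + BLAS matrix products; all gradients are exact.
#
# Tensors are dense double arrays dim = c(H, W, C). Parameters live in a
# named list on the tape; gradients accumulate under the same names.

.conv_index_cache <- new.env(parent = emptyenv())

# Gather index for im2col: (H*W) x (k*k) matrix of source linear indices,
# 0 marking zero-padded positions. Memoised on (H, W, k, pad).
conv_gather_index <- function(H, W, k, pad) {
  key <- paste(H, W, k, pad, sep = "_")
  hit <- .conv_index_cache[[key]]
  if (!is.null(hit)) return(hit)
  h <- (k - 1L) %/% 2L
  offs <- expand.grid(di = -h:h, dj = -h:h)   # di fastest, matching weight layout
  idx <- matrix(0L, H * W, nrow(offs))
  r0 <- rep.int(seq_len(H), W)
  c0 <- rep(seq_len(W), each = H)
  for (o in seq_len(nrow(offs))) {
    r <- r0 + offs$di[o]; cc <- c0 + offs$dj[o]
    if (pad == "wrap") {
      r <- (r - 1L) %% H + 1L; cc <- (cc - 1L) %% W + 1L
      idx[, o] <- r + (cc - 1L) * H
    } else {
      ok <- r >= 1L & r <= H & cc >= 1L & cc <= W
      v <- integer(H * W)
      v[ok] <- r[ok] + (cc[ok] - 1L) * H
      idx[, o] <- v
    }
  }
  .conv_index_cache[[key]] <- idx
  idx
}

# x: (H, W, C) -> (H*W) x (k*k*C) patch matrix (offset fastest, then channel).
im2col <- function(x, k, pad) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  idx <- conv_gather_index(H, W, k, pad)
  .cpp_gather_cols(matrix(x, H * W, C), idx)
}

# Scatter-add the patch-gradient matrix back onto the input grid.
col2im <- function(dcols, H, W, C, k, pad) {
  idx <- conv_gather_index(H, W, k, pad)
  array(.cpp_scatter_cols(dcols, idx, C), c(H, W, C))
}

tape_new <- function(params, training = TRUE) {
  tp <- new.env(parent = emptyenv())
  tp$params <- params
  tp$grads <- list()
  tp$nodes <- list()
  tp$training <- training
  tp
}

# force `id` before touching tp$nodes: evaluating a lazily passed op call
# can itself push nodes onto the tape
tp_value <- function(tp, id) {
  force(id)
  tp$nodes[[id]]$value
}

tp_push <- function(tp, value, parents = integer(), backward = NULL) {
  force(value); force(parents)
  id <- length(tp$nodes) + 1L
  tp$nodes[[id]] <- list(value = value, parents = parents, backward = backward)
  id
}

tp_accum_grad <- function(tp, name, g) {
  cur <- tp$grads[[name]]
  tp$grads[[name]] <- if (is.null(cur)) g else cur + g
}

tp_input <- function(tp, x) tp_push(tp, x)

# Convolution, stride 1, same padding. Weight dims (k, k, Cin, Cout).
tp_conv <- function(tp, xid, wname, bname, pad = "zero") {
  x <- tp_value(tp, xid)
  w <- tp$params[[wname]]; b <- tp$params[[bname]]
  k <- dim(w)[1]; Cin <- dim(w)[3]; Cout <- dim(w)[4]
  d <- dim(x); H <- d[1]; W <- d[2]
  stopifnot(d[3] == Cin)
  wmat <- matrix(w, k * k * Cin, Cout)
  ymat <- im2col(x, k, pad) %*% wmat
  ymat <- sweep(ymat, 2L, b, `+`)
  tp_push(tp, array(ymat, c(H, W, Cout)), parents = xid,
          backward = function(g) {
            gm <- matrix(g, H * W, Cout)
            cols <- im2col(x, k, pad)
            tp_accum_grad(tp, wname, array(crossprod(cols, gm), dim(w)))
            tp_accum_grad(tp, bname, colSums(gm))
            list(col2im(gm %*% t(wmat), H, W, Cin, k, pad))
          })
}

tp_relu <- function(tp, xid) {
  x <- tp_value(tp, xid)
  y <- x * (x > 0)
  tp_push(tp, y, parents = xid, backward = function(g) list(g * (x > 0)))
}

tp_sigmoid <- function(tp, xid) {
  x <- tp_value(tp, xid)
  y <- 1 / (1 + exp(-x))
  tp_push(tp, y, parents = xid, backward = function(g) list(g * y * (1 - y)))
}

# Per-channel normalisation over the spatial plane with learned scale and
# shift. With single-image batches this is batch normalisation computed on
# the batch actually seen (equivalently instance normalisation); the same
# statistics are used at inference, keeping prediction deterministic and
# translation-covariant.
tp_bn <- function(tp, xid, gname, bname, eps = 1e-5) {
  x <- tp_value(tp, xid)
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- H * W
  gam <- tp$params[[gname]]; bet <- tp$params[[bname]]
  xm <- matrix(x, N, C)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  va <- colSums(xc * xc) / N
  isd <- 1 / sqrt(va + eps)
  xh <- sweep(xc, 2L, isd, `*`)
  ym <- sweep(sweep(xh, 2L, gam, `*`), 2L, bet, `+`)
  tp_push(tp, array(ym, d), parents = xid,
          backward = function(g) {
            gm <- matrix(g, N, C)
            tp_accum_grad(tp, gname, colSums(gm * xh))
            tp_accum_grad(tp, bname, colSums(gm))
            dxh <- sweep(gm, 2L, gam, `*`)
            # dx = isd/N * (N*dxh - sum(dxh) - xh * sum(dxh*xh))
            s1 <- colSums(dxh); s2 <- colSums(dxh * xh)
            dx <- sweep(N * dxh, 2L, s1) - sweep(xh, 2L, s2, `*`)
            dx <- sweep(dx, 2L, isd / N, `*`)
            list(array(dx, d))
          })
}

tp_maxpool <- function(tp, xid) {
  x <- tp_value(tp, xid)
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  if (H %% 2L || W %% 2L) err_shape("max pooling requires even spatial dims")
  x5 <- array(x, c(2L, H %/% 2L, 2L, W %/% 2L, C))
  s11 <- x5[1, , 1, , , drop = FALSE]; dim(s11) <- c(H %/% 2L, W %/% 2L, C)
  s21 <- x5[2, , 1, , , drop = FALSE]; dim(s21) <- dim(s11)
  s12 <- x5[1, , 2, , , drop = FALSE]; dim(s12) <- dim(s11)
  s22 <- x5[2, , 2, , , drop = FALSE]; dim(s22) <- dim(s11)
  y <- pmax(s11, s21, s12, s22)
  m11 <- s11 == y
  m21 <- (s21 == y) & !m11
  m12 <- (s12 == y) & !(m11 | m21)
  m22 <- !(m11 | m21 | m12)
  tp_push(tp, y, parents = xid,
          backward = function(g) {
            d5 <- array(0, c(2L, H %/% 2L, 2L, W %/% 2L, C))
            d5[1, , 1, , ] <- g * m11
            d5[2, , 1, , ] <- g * m21
            d5[1, , 2, , ] <- g * m12
            d5[2, , 2, , ] <- g * m22
            list(array(d5, d))
          })
}

# Transposed convolution, kernel 2x2, stride 2 (learned 2x upsampling).
# Weight dims (2, 2, Cin, Cout).
tp_upconv <- function(tp, xid, wname, bname) {
  x <- tp_value(tp, xid)
  w <- tp$params[[wname]]; b <- tp$params[[bname]]
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]; Cout <- dim(w)[4]
  xm <- matrix(x, H * W, Cin)
  y <- array(0, c(2L * H, 2L * W, Cout))
  for (a in 1:2) for (cc in 1:2) {
    slab <- xm %*% matrix(w[a, cc, , ], Cin, Cout)
    y[seq(a, 2L * H, 2L), seq(cc, 2L * W, 2L), ] <- array(slab, c(H, W, Cout))
  }
  y <- sweep(y, 3L, b, `+`)
  tp_push(tp, y, parents = xid,
          backward = function(g) {
            dx <- matrix(0, H * W, Cin)
            for (a in 1:2) for (cc in 1:2) {
              gs <- g[seq(a, 2L * H, 2L), seq(cc, 2L * W, 2L), , drop = FALSE]
              gm <- matrix(gs, H * W, Cout)
              dx <- dx + gm %*% t(matrix(w[a, cc, , ], Cin, Cout))
              dw <- crossprod(xm, gm)
              dwa <- array(0, dim(w)); dwa[a, cc, , ] <- dw
              tp_accum_grad(tp, wname, dwa)
            }
            tp_accum_grad(tp, bname, apply(g, 3L, sum))
            list(array(dx, d))
          })
}

tp_concat <- function(tp, aid, bid) {
  a <- tp_value(tp, aid); b <- tp_value(tp, bid)
  da <- dim(a); db <- dim(b)
  if (any(da[1:2] != db[1:2])) err_shape("concat inputs differ in spatial shape")
  y <- array(0, c(da[1], da[2], da[3] + db[3]))
  y[, , seq_len(da[3])] <- a
  y[, , da[3] + seq_len(db[3])] <- b
  tp_push(tp, y, parents = c(aid, bid),
          backward = function(g)
            list(g[, , seq_len(da[3]), drop = FALSE],
                 g[, , da[3] + seq_len(db[3]), drop = FALSE]))
}

tp_add <- function(tp, aid, bid) {
  a <- tp_value(tp, aid); b <- tp_value(tp, bid)
  if (any(dim(a) != dim(b))) err_shape("add inputs differ in shape")
  tp_push(tp, a + b, parents = c(aid, bid), backward = function(g) list(g, g))
}

# x (H, W, C) * coef (H, W, 1), broadcast over channels.
tp_mul_coef <- function(tp, xid, aid) {
  x <- tp_value(tp, xid); a <- tp_value(tp, aid)
  d <- dim(x)
  if (any(dim(a)[1:2] != d[1:2]) || dim(a)[3] != 1L)
    err_shape("coefficient map must be H x W x 1 matching the gated features")
  am <- a[, , 1]
  y <- x * as.vector(am)
  tp_push(tp, y, parents = c(xid, aid),
          backward = function(g) {
            da <- array(rowSums(matrix(g * x, prod(d[1:2]), d[3])), c(d[1], d[2], 1L))
            list(g * as.vector(am), da)
          })
}

# Nearest-neighbour upsampling by an integer factor (used to resample a
# coarse gating signal onto the skip resolution).
tp_upsample_nn <- function(tp, xid, factor) {
  x <- tp_value(tp, xid)
  d <- dim(x)
  ri <- rep(seq_len(d[1]), each = factor)
  ci <- rep(seq_len(d[2]), each = factor)
  y <- x[ri, ci, , drop = FALSE]
  tp_push(tp, y, parents = xid,
          backward = function(g) {
            dx <- array(0, d)
            for (a in seq_len(factor)) for (b in seq_len(factor))
              dx <- dx + g[seq(a, d[1] * factor, factor),
                           seq(b, d[2] * factor, factor), , drop = FALSE]
            list(dx)
          })
}

# Backward pass from a scalar-valued seed gradient on node `from_id`.
tp_backward <- function(tp, from_id, seed_grad) {
  n <- length(tp$nodes)
  gr <- vector("list", n)
  gr[[from_id]] <- seed_grad
  for (id in seq(n, 1L)) {
    g <- gr[[id]]
    if (is.null(g)) next
    nd <- tp$nodes[[id]]
    if (is.null(nd$backward)) next
    pg <- nd$backward(g)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[j]
      if (is.null(pg[[j]])) next
      gr[[p]] <- if (is.null(gr[[p]])) pg[[j]] else gr[[p]] + pg[[j]]
    }
    gr[[id]] <- NULL   # free memory as we walk back
  }
  invisible(tp)
}
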