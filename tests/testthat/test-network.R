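test_that("all three builders emit shape-preserving per-pixel softmax outputs", {
  set.seed(3)
  x <- matrix(runif(32 * 32), 32, 32)
  for (build in list(build_asw_net, build_sw_net, build_u_net)) {
    mod <- build(network_config(base_filters = 2L, rng_seed = 4L))
    p <- predict_probmap(mod, x)
    expect_equal(dim(p), c(32L, 32L, 3L))
    expect_true(all(p >= 0))
    expect_lt(max(abs(p[, , 1] + p[, , 2] + p[, , 3] - 1)), 1e-5)
  }
})

test_that("attention gates add parameters: ASW > SW at equal configuration", {
  cfg <- network_config(base_filters = 4L, rng_seed = 1L)
  asw <- build_asw_net(cfg)
  sw <- build_sw_net(cfg)
  expect_gt(asw$parameter_count, sw$parameter_count)
  expect_true(any(grepl("^g[123]\\.", names(asw$params))))
  expect_false(any(grepl("^g[123]\\.", names(sw$params))))
  expect_false(any(grepl("^g[123]\\.", names(build_u_net(cfg)$params))))
})

test_that("forward passes are deterministic given the initialisation seed", {
  x <- matrix(seq(0, 1, length.out = 24 * 24), 24, 24)
  m1 <- build_asw_net(network_config(base_filters = 2L, rng_seed = 7L))
  m2 <- build_asw_net(network_config(base_filters = 2L, rng_seed = 7L))
  expect_identical(predict_probmap(m1, x)[, , ], predict_probmap(m2, x)[, , ])
  expect_identical(predict_probmap(m1, x)[, , ], predict_probmap(m1, x)[, , ])
})

test_that("inputs not divisible by 8 error at the raw forward but pad in predict", {
  mod <- build_sw_net(network_config(base_filters = 2L))
  expect_error(forward_logits(mod, matrix(0, 20, 20)), class = "aswnet_shape_error")
  p <- predict_probmap(mod, matrix(runif(20 * 27), 20, 27))
  expect_equal(dim(p)[1:2], c(20L, 27L))
})

test_that("attention gate coefficients live in (0,1) and gate multiplicatively", {
  set.seed(5)
  skip <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  gating <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  g <- attention_gate(skip, gating, rng_seed = 2L)
  expect_true(all(g$coefficients > 0 & g$coefficients < 1))
  expect_equal(g$gated, skip * as.vector(g$coefficients))

  # zeroed final projection: coefficients collapse to sigmoid(0) = 0.5
  f <- 2L
  params <- list(wx = array(rnorm(4 * f), c(1, 1, 4, f)),
                 wg = array(rnorm(4 * f), c(1, 1, 4, f)), wg_b = numeric(f),
                 psi = array(0, c(1, 1, f, 1)), psi_b = 0)
  g0 <- attention_gate(skip, gating, params)
  expect_true(all(g0$coefficients == 0.5))

  # hand-computed elementwise product on a 2x2 toy
  skip2 <- array(c(1, 2, 3, 4), c(2, 2, 1))
  params2 <- list(wx = array(1, c(1, 1, 1, 1)), wg = array(0, c(1, 1, 1, 1)),
                  wg_b = 0, psi = array(1, c(1, 1, 1, 1)), psi_b = 0)
  g2 <- attention_gate(skip2, array(0, c(2, 2, 1)), params2)
  coef_expect <- 1 / (1 + exp(-pmax(c(1, 2, 3, 4), 0)))
  expect_equal(as.vector(g2$coefficients), coef_expect)
  expect_equal(as.vector(g2$gated), c(1, 2, 3, 4) * coef_expect)

  # coarse gating is upsampled to the skip resolution
  gc <- attention_gate(skip, array(rnorm(8 * 8 * 2), c(8, 8, 2)), rng_seed = 3L)
  expect_equal(dim(gc$coefficients), c(16L, 16L))
})

test_that("tape gradients match numerical differentiation", {
  set.seed(9)
  mod <- build_asw_net(network_config(base_filters = 2L, use_batchnorm = TRUE,
                                      rng_seed = 13L))
  x <- matrix(runif(16 * 16), 16, 16)
  lab <- three_class_label(matrix(sample(0:2, 256, TRUE), 16, 16))
  w <- class_weights(1, 2, 3)
  loss_at <- function(m) {
    fw <- aswnet:::net_forward(m, x, training = TRUE)
    aswnet:::wce_from_logits(aswnet:::tp_value(fw$tape, fw$logits), lab, w)$loss
  }
  r <- aswnet:::sample_loss_and_grads(mod, x, lab, w)
  eps <- 1e-5
  for (nm in c("c0.conv1.w", "g1.psi.w", "u3.w", "head.b", "c6.bn2.g")) {
    i <- which.max(abs(r$grads[[nm]]))           # probe the largest entry
    mp <- mod; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
    mm <- mod; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
    num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
    expect_equal(r$grads[[nm]][i], num, tolerance = 1e-4)
  }
})

test_that("wrap padding makes logits covariant under translation by 8 pixels", {
  set.seed(4)
  mod <- build_sw_net(network_config(base_filters = 2L, use_batchnorm = FALSE,
                                     padding = "wrap", rng_seed = 6L))
  x <- matrix(runif(32 * 32), 32, 32)
  shift8 <- function(m) m[c(25:32, 1:24), c(25:32, 1:24), , drop = FALSE]
  l1 <- forward_logits(mod, x)
  l2 <- forward_logits(mod, x[c(25:32, 1:24), c(25:32, 1:24)])
  expect_equal(l2, shift8(l1), tolerance = 1e-10)
})
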