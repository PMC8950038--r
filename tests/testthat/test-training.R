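uniform_prob <- function(H, W) prob_map(array(1 / 3, c(H, W, 3)))

test_that("weighted cross-entropy has its closed-form values", {
  lab <- three_class_label(matrix(sample(0:2, 64, TRUE), 8, 8))
  # one-hot on the target: loss 0 regardless of weights
  a <- array(0, c(8, 8, 3))
  for (k in 0:2) a[, , k + 1] <- (unclass(lab) == k) * 1
  expect_equal(weighted_cross_entropy(prob_map(a), lab, class_weights(1, 5, 9)), 0,
               tolerance = 1e-6)
  # uniform prediction, unit weights: ln 3
  expect_equal(weighted_cross_entropy(uniform_prob(8, 8), lab), log(3))
  # 2-pixel toy, weights (1,2,1), hand-evaluated
  probs <- array(0, c(1, 2, 3))
  probs[1, 1, ] <- c(0.7, 0.2, 0.1)
  probs[1, 2, ] <- c(0.1, 0.6, 0.3)
  toy_lab <- three_class_label(matrix(c(0L, 1L), 1, 2))
  expected <- -(1 * log(0.7) + 2 * log(0.6)) / 3
  expect_equal(weighted_cross_entropy(prob_map(probs), toy_lab,
                                      class_weights(1, 2, 1)), expected)
  expect_error(weighted_cross_entropy(uniform_prob(4, 4),
                                      three_class_label(matrix(0L, 5, 5))),
               class = "aswnet_shape_error")
})

test_that("unit weights reduce to plain cross-entropy and the loss is scale-stable", {
  set.seed(6)
  a <- array(runif(8 * 8 * 3), c(8, 8, 3))
  s <- a[, , 1] + a[, , 2] + a[, , 3]
  for (k in 1:3) a[, , k] <- a[, , k] / s
  lab <- three_class_label(matrix(sample(0:2, 64, TRUE), 8, 8))
  p <- prob_map(a)
  plain <- -mean(log(pmax(vapply(seq_len(64), function(i) {
    a[(i - 1) %% 8 + 1, (i - 1) %/% 8 + 1, unclass(lab)[i] + 1]
  }, 0), 1e-7)))
  expect_equal(weighted_cross_entropy(p, lab), plain)

  # duplicating every pixel leaves the normalised loss unchanged
  a2 <- array(0, c(8, 16, 3)); a2[, 1:8, ] <- a; a2[, 9:16, ] <- a
  lab2 <- three_class_label(cbind(unclass(lab), unclass(lab)))
  w <- class_weights(1, 3, 7)
  expect_equal(weighted_cross_entropy(prob_map(a2), lab2, w),
               weighted_cross_entropy(p, lab, w))
})

test_that("a 10-epoch plateau triggers early stopping with the best epoch retained", {
  val <- c(3, 2, rep(2, 10))          # improvement at epoch 2, then flat
  r <- early_stopping_epoch(val, patience = 10L)
  expect_true(r$stopped_early)
  expect_equal(r$best_epoch, 2L)
  expect_equal(r$stop_epoch, 12L)

  r2 <- early_stopping_epoch(c(3, 2.5, 2.0, 1.5), patience = 10L)
  expect_false(r2$stopped_early)
  expect_equal(r2$best_epoch, 4L)

  # improvements below the delta do not reset patience
  r3 <- early_stopping_epoch(2 - cumsum(rep(1e-9, 12)), patience = 10L)
  expect_true(r3$stopped_early)
})

test_that("train_model respects epoch bounds, stops on plateaus, and restores best weights", {
  set.seed(12)
  mk <- function(seed) {
    s <- generate_nuclei_image(synth_config(image_height = 32L, image_width = 32L,
                                            n_nuclei = 2L, radius_range = c(4, 6),
                                            rng_seed = seed))
    list(image = normalize_grayscale(s$image),
         label = instance_to_three_class(s$truth, 1L))
  }
  tr <- lapply(1:2, mk); va <- lapply(3:4, mk)
  mod <- build_sw_net(network_config(base_filters = 2L, rng_seed = 2L))

  one <- train_model(mod, tr, va, train_config(max_epochs = 1L))
  expect_equal(nrow(one$history), 1L)
  expect_false(one$stopped_early)

  fit <- train_model(mod, tr, va,
                     train_config(max_epochs = 40L, patience_epochs = 3L,
                                  initial_learning_rate = 5e-3, rng_seed = 5L))
  expect_equal(fit$best_epoch, which.min(fit$history$val_loss))
  # the returned model really carries the best-epoch weights
  w <- train_config()$weights
  val_now <- mean(vapply(va, function(s) {
    fw <- aswnet:::net_forward(fit$model, unclass(s$image), training = FALSE)
    aswnet:::wce_from_logits(aswnet:::tp_value(fw$tape, fw$logits), s$label, w)$loss
  }, 0))
  expect_equal(val_now, min(fit$history$val_loss), tolerance = 1e-8)

  expect_error(train_model(mod, list(), va, train_config()),
               class = "aswnet_empty_dataset")
})

test_that("a tiny network overfits a single synthetic image", {
  s <- generate_nuclei_image(synth_config(image_height = 64L, image_width = 64L,
                                          n_nuclei = 4L, radius_range = c(8, 12),
                                          rng_seed = 3L))
  img <- normalize_grayscale(s$image)
  lab <- instance_to_three_class(s$truth, 2L)
  w <- compute_class_weights(lab)
  mod <- build_asw_net(network_config(base_filters = 4L, rng_seed = 1L))
  smp <- list(image = img, label = lab)
  fit <- train_model(mod, list(smp), list(smp),
                     train_config(max_epochs = 60L, patience_epochs = 60L,
                                  initial_learning_rate = 2e-3, weights = w,
                                  rng_seed = 1L))
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
})

test_that("checkpoints round-trip the model and carry a JSON sidecar", {
  d <- withr::local_tempdir()
  mod <- build_asw_net(network_config(base_filters = 2L, rng_seed = 8L))
  p <- file.path(d, "ck.rds")
  save_checkpoint(mod, p)
  expect_true(file.exists(paste0(p, ".json")))
  side <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(side$variant, "asw")
  expect_equal(side$parameter_count, mod$parameter_count)
  back <- load_checkpoint(p)
  x <- matrix(runif(16 * 16), 16, 16)
  expect_identical(predict_probmap(back, x)[, , ], predict_probmap(mod, x)[, , ])
})
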