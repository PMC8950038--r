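# Training: weighted cross-entropy over the three classes, RMSProp
# updates, early stopping on a validation plateau with save-best weights.

#' Training configuration
#'
#' @param max_epochs Upper bound on epochs.
#' @param batch_size Images per parameter update (gradients averaged).
#' @param initial_learning_rate RMSProp step size; the optimiser's
#'   per-parameter scaling provides the dynamic adaptation.
#' @param patience_epochs Stop when validation loss has not improved for
#'   this many consecutive epochs (default 10).
#' @param weights A [class_weights()] for the loss.
#' @param rng_seed Seed controlling shuffling and any augmentation.
#' @param augment Optional [preprocess_config()]; when supplied, each
#'   training image is augmented with a fresh random rotation/flip each
#'   epoch.
#' @return A `train_config` list.
#' @export
train_config <- function(max_epochs = 50L, batch_size = 1L,
                         initial_learning_rate = 1e-3,
                         patience_epochs = 10L,
                         weights = class_weights(),
                         rng_seed = 1L, augment = NULL) {
  stopifnot(max_epochs >= 1, batch_size >= 1, patience_epochs >= 1,
            initial_learning_rate > 0, inherits(weights, "class_weights"))
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 initial_learning_rate = initial_learning_rate,
                 patience_epochs = as.integer(patience_epochs),
                 weights = weights, rng_seed = as.integer(rng_seed),
                 augment = augment),
            class = "train_config")
}

#' Weighted cross-entropy loss
#'
#' `-sum_p w[c(p)] log probs[p, c(p)] / sum_p w[c(p)]`, with probabilities
#' clipped below at 1e-7 before the log. Normalising by the summed weights
#' (not the pixel count) keeps the loss scale comparable across
#' class-imbalance settings; unit weights recover plain cross-entropy.
#'
#' @param probs A [prob_map()] (or H x W x 3 array).
#' @param target A [three_class_label()] of the same spatial shape.
#' @param weights A [class_weights()].
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(probs, target, weights = class_weights()) {
  if (any(dim(probs)[1:2] != dim(target))) err_shape("probs and target shapes differ")
  w <- c(weights$w_background, weights$w_interior, weights$w_boundary)
  cls <- as.vector(unclass(target)) + 1L
  n <- length(cls)
  pm <- matrix(probs, n, 3L)
  p_true <- pm[cbind(seq_len(n), cls)]
  wp <- w[cls]
  -sum(wp * log(pmax(p_true, 1e-7))) / sum(wp)
}

# Loss + gradient wrt logits for the fused softmax/cross-entropy head.
wce_from_logits <- function(logits, target, weights) {
  w <- c(weights$w_background, weights$w_interior, weights$w_boundary)
  d <- dim(logits); n <- d[1] * d[2]
  p <- softmax3(logits)
  pm <- matrix(p, n, 3L)
  cls <- as.vector(unclass(target)) + 1L
  wp <- w[cls]; sw <- sum(wp)
  loss <- -sum(wp * log(pmax(pm[cbind(seq_len(n), cls)], 1e-7))) / sw
  onehot <- matrix(0, n, 3L)
  onehot[cbind(seq_len(n), cls)] <- 1
  dlog <- (pm - onehot) * (wp / sw)
  list(loss = loss, dlogits = array(dlog, d), probs = p)
}

#' Best epoch and stopping epoch under a patience rule
#'
#' Validation loss must improve on the best seen so far by more than
#' `min_delta` to reset the patience counter; after `patience` consecutive
#' non-improving epochs training stops.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param patience Patience window in epochs.
#' @param min_delta Minimal decrease that counts as improvement.
#' @return List with `best_epoch`, `stop_epoch` (last epoch that would
#'   run, `length(val_losses)` if never triggered) and `stopped_early`.
#' @export
early_stopping_epoch <- function(val_losses, patience = 10L, min_delta = 1e-6) {
  best <- Inf; best_epoch <- 0L; wait <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best - min_delta) {
      best <- val_losses[e]; best_epoch <- e; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience)
        return(list(best_epoch = best_epoch, stop_epoch = e, stopped_early = TRUE))
    }
  }
  list(best_epoch = best_epoch, stop_epoch = length(val_losses), stopped_early = FALSE)
}

rmsprop_step <- function(params, grads, cache, lr, rho = 0.9, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    c0 <- cache[[nm]]
    if (is.null(c0)) c0 <- g * 0
    c0 <- rho * c0 + (1 - rho) * g * g
    cache[[nm]] <- c0
    params[[nm]] <- params[[nm]] - lr * g / (sqrt(c0) + eps)
  }
  list(params = params, cache = cache)
}

as_train_sample <- function(s) {
  stopifnot(is.list(s), !is.null(s$image), !is.null(s$label))
  s
}

sample_loss_and_grads <- function(model, image, label, weights) {
  fw <- net_forward(model, unclass(image), training = TRUE)
  head <- wce_from_logits(tp_value(fw$tape, fw$logits), label, weights)
  tp_backward(fw$tape, fw$logits, head$dlogits)
  list(loss = head$loss, grads = fw$tape$grads)
}

#' Train a model with RMSProp, early stopping and save-best weights
#'
#' Samples are lists with `image` (normalised matrix or float
#' [gray_image()]) and `label` ([three_class_label()]). Each epoch runs
#' all training samples (optionally augmented) in a shuffled order,
#' averaging gradients over `batch_size` images per update, then scores
#' the validation set. When the validation loss fails to improve for
#' `patience_epochs` consecutive epochs, training stops and the weights of
#' the best validation epoch are restored.
#'
#' @param model An `aswnet_model` from one of the builders.
#' @param train_set,val_set Non-empty lists of samples.
#' @param config A [train_config()].
#' @param verbose Print a line per epoch.
#' @return List with `model` (best weights), `history` (data.frame epoch /
#'   train_loss / val_loss), `best_epoch`, `stopped_early`.
#' @export
train_model <- function(model, train_set, val_set, config = train_config(),
                        verbose = FALSE) {
  if (!length(train_set) || !length(val_set))
    err_empty_dataset("train and validation sets must be non-empty")
  train_set <- lapply(train_set, as_train_sample)
  val_set <- lapply(val_set, as_train_sample)
  w <- config$weights
  cache <- list()
  hist_tr <- hist_va <- numeric(0)
  best_params <- model$params; best_val <- Inf; best_epoch <- 0L; wait <- 0L
  stopped_early <- FALSE
  with_seed(config$rng_seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(length(train_set))
      ep_loss <- 0; nb <- 0L
      i <- 1L
      while (i <= length(ord)) {
        take <- ord[i:min(i + config$batch_size - 1L, length(ord))]
        acc <- NULL; bl <- 0
        for (j in take) {
          s <- train_set[[j]]
          if (!is.null(config$augment)) {
            aug <- augment_pair(gray_image(pmin(pmax(unclass(s$image), 0), 1), "float"),
                                s$label, config$augment,
                                rng_seed = sample.int(2^30, 1L))
            s <- list(image = aug$image, label = aug$label)
          }
          r <- sample_loss_and_grads(model, s$image, s$label, w)
          if (!is.finite(r$loss))
            err_divergence(sprintf("non-finite loss at epoch %d", epoch))
          bl <- bl + r$loss
          acc <- if (is.null(acc)) r$grads
          else { for (nm in names(r$grads)) acc[[nm]] <- (acc[[nm]] %||% 0) + r$grads[[nm]]; acc }
        }
        nk <- length(take)
        for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / nk
        st <- rmsprop_step(model$params, acc, cache, config$initial_learning_rate)
        model$params <- st$params; cache <- st$cache
        ep_loss <- ep_loss + bl; nb <- nb + nk
        i <- i + config$batch_size
      }
      tr_loss <- ep_loss / nb
      va_loss <- mean(vapply(val_set, function(s) {
        fw <- net_forward(model, unclass(s$image), training = FALSE)
        wce_from_logits(tp_value(fw$tape, fw$logits), s$label, w)$loss
      }, 0))
      if (!is.finite(va_loss)) err_divergence(sprintf("non-finite validation loss at epoch %d", epoch))
      hist_tr <- c(hist_tr, tr_loss); hist_va <- c(hist_va, va_loss)
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f", epoch, tr_loss, va_loss))
      if (va_loss < best_val - 1e-6) {
        best_val <- va_loss; best_epoch <- epoch; best_params <- model$params; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience_epochs) { stopped_early <- TRUE; break }
      }
    }
  })
  model$params <- best_params
  list(model = model,
       history = data.frame(epoch = seq_along(hist_tr),
                            train_loss = hist_tr, val_loss = hist_va),
       best_epoch = best_epoch, stopped_early = stopped_early)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a model checkpoint
#'
#' The weights go into an RDS file; a JSON sidecar (`<path>.json`) records
#' the variant, the network configuration and the parameter count.
#'
#' @param model An `aswnet_model`.
#' @param path Destination `.rds` path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  if (!dir.exists(dirname(path))) err_io(sprintf("directory '%s' does not exist", dirname(path)))
  saveRDS(list(variant = model$variant, config = unclass(model$config),
               params = model$params), path)
  side <- unclass(model$config)
  side$variant <- model$variant
  side$parameter_count <- model$parameter_count
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) err_not_found(sprintf("checkpoint '%s' does not exist", path))
  ck <- readRDS(path)
  cfg <- structure(ck$config, class = "network_config")
  new_model(ck$variant, cfg, ck$params)
}
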