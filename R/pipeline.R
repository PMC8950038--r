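# Pipeline wiring: YAML-configured generate -> train -> predict ->
# evaluate -> visualize commands. A thin Rscript front end lives in
# inst/cli/aswnet.R; these functions are the programmatic interface.

#' Default pipeline configuration
#'
#' Nested configuration blocks for every stage (synth, preprocess, model,
#' train, postprocess) plus the run directory. [load_pipeline_config()]
#' reads the same structure from YAML and merges it over these defaults.
#'
#' @param run_dir Directory for datasets, checkpoints and reports.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(run_dir = "aswnet_run") {
  structure(list(
    schema_version = 1L,
    run_dir = run_dir,
    synth = list(preset = "bbbc039-like", image_height = 256L, image_width = 256L,
                 n_train = 100L, n_val = 50L, n_test = 50L, rng_seed = 1L),
    preprocess = list(norm = list(low = 0.1, high = 99.9),
                      labels = list(boundary_width = 2L),
                      augment = list(rotations = c(0, 90, 180, 270),
                                     flips = c("horizontal", "vertical"))),
    model = list(variant = "asw", base_filters = 16L, kernel_size = 3L,
                 attention = TRUE, batchnorm = TRUE, rng_seed = 1L),
    train = list(max_epochs = 50L, batch_size = 1L, learning_rate = 1e-3,
                 patience = 10L, rng_seed = 1L, augment = TRUE),
    postprocess = list(method = "interior_expansion", seed_threshold = 0.5,
                       connectivity = 8L)),
    class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Keys present in the file override the defaults of [pipeline_config()];
#' everything else keeps its default, so minimal configs stay minimal.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config` list.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) err_not_found(sprintf("config '%s' does not exist", path))
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(pipeline_config()), user)
  structure(cfg, class = "pipeline_config")
}

preprocess_config_from <- function(cfg) {
  preprocess_config(norm_low_percentile = cfg$preprocess$norm$low,
                    norm_high_percentile = cfg$preprocess$norm$high,
                    boundary_width = cfg$preprocess$labels$boundary_width,
                    augment_rotations = cfg$preprocess$augment$rotations,
                    augment_flips = cfg$preprocess$augment$flips)
}

network_config_from <- function(cfg) {
  network_config(base_filters = cfg$model$base_filters,
                 kernel_size = cfg$model$kernel_size,
                 use_attention = isTRUE(cfg$model$attention),
                 use_batchnorm = isTRUE(cfg$model$batchnorm),
                 rng_seed = cfg$model$rng_seed)
}

postprocess_config_from <- function(cfg) {
  postprocess_config(seed_threshold = cfg$postprocess$seed_threshold,
                     connectivity = cfg$postprocess$connectivity,
                     method = cfg$postprocess$method)
}

#' Generate a synthetic dataset for a pipeline run
#'
#' @param config A `pipeline_config`.
#' @param quiet Suppress the log line.
#' @return Invisibly, the manifest data.frame.
#' @export
cmd_generate <- function(config = pipeline_config(), quiet = FALSE) {
  sy <- config$synth
  extra <- sy[setdiff(names(sy), c("preset", "n_train", "n_val", "n_test"))]
  sc <- do.call(synth_preset, c(list(name = sy$preset), extra))
  out <- file.path(config$run_dir, "data")
  man <- generate_dataset(sc, sy$n_train, sy$n_val, sy$n_test, out)
  if (!quiet) message(sprintf("wrote %d samples; manifest at %s",
                              nrow(man), file.path(out, "manifest.tsv")))
  invisible(man)
}

load_split <- function(data_dir, manifest, split, pre_cfg) {
  rows <- manifest[manifest$split == split, , drop = FALSE]
  lapply(seq_len(nrow(rows)), function(i) {
    img <- read_image(file.path(data_dir, rows$image_path[i]))
    msk <- read_label_map(file.path(data_dir, rows$mask_path[i]))
    list(image = normalize_grayscale(img, pre_cfg),
         label = instance_to_three_class(msk, pre_cfg$boundary_width),
         truth = msk)
  })
}

#' Train a model for a pipeline run
#'
#' Reads the run's manifest, normalises images, renders three-class
#' labels, computes inverse-frequency class weights, trains with RMSProp
#' and early stopping, and writes the best checkpoint (plus a JSON
#' sidecar and a CSV training log) under `<run_dir>/model/`.
#'
#' @param config A `pipeline_config`.
#' @param quiet Suppress progress lines.
#' @return Invisibly, the [train_model()] result.
#' @export
cmd_train <- function(config = pipeline_config(), quiet = FALSE) {
  data_dir <- file.path(config$run_dir, "data")
  man_path <- file.path(data_dir, "manifest.tsv")
  if (!file.exists(man_path)) err_not_found(sprintf("manifest '%s' not found; run cmd_generate first", man_path))
  man <- read_manifest(man_path)
  pre <- preprocess_config_from(config)
  tr <- load_split(data_dir, man, "train", pre)
  va <- load_split(data_dir, man, "val", pre)
  weights <- compute_class_weights(lapply(tr, `[[`, "label"))
  model <- switch(config$model$variant,
                  asw = build_asw_net(network_config_from(config)),
                  sw = build_sw_net(network_config_from(config)),
                  unet = build_u_net(network_config_from(config)))
  tc <- train_config(max_epochs = config$train$max_epochs,
                     batch_size = config$train$batch_size,
                     initial_learning_rate = config$train$learning_rate,
                     patience_epochs = config$train$patience,
                     weights = weights, rng_seed = config$train$rng_seed,
                     augment = if (isTRUE(config$train$augment)) pre else NULL)
  fit <- train_model(model, tr, va, tc, verbose = !quiet)
  mdir <- file.path(config$run_dir, "model")
  dir.create(mdir, showWarnings = FALSE, recursive = TRUE)
  save_checkpoint(fit$model, file.path(mdir, "best.rds"))
  utils::write.table(cbind(fit$history, lr = tc$initial_learning_rate),
                     file.path(mdir, "history.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  if (!quiet) message(sprintf("best epoch %d (val loss %.5f)%s", fit$best_epoch,
                              min(fit$history$val_loss),
                              if (fit$stopped_early) ", stopped early" else ""))
  invisible(fit)
}

#' Predict probability maps and instance masks for a set of images
#'
#' Per image: normalise, forward through the network (reflect-padding to
#' a multiple of 8 and cropping back as needed), save the probability map
#' as a 3-page float TIFF and the post-processed instance mask as a label
#' TIFF.
#'
#' @param config A `pipeline_config`.
#' @param checkpoint Path to a checkpoint from [cmd_train()]; default is
#'   the run's `model/best.rds`.
#' @param images Character vector of image paths; default is the run's
#'   test split.
#' @param out_dir Output directory; default `<run_dir>/predictions`.
#' @param quiet Suppress the log line.
#' @return Invisibly, a data.frame of written file paths.
#' @export
cmd_predict <- function(config = pipeline_config(), checkpoint = NULL,
                        images = NULL, out_dir = NULL, quiet = FALSE) {
  if (is.null(checkpoint)) checkpoint <- file.path(config$run_dir, "model", "best.rds")
  model <- load_checkpoint(checkpoint)
  if (is.null(images)) {
    man <- read_manifest(file.path(config$run_dir, "data", "manifest.tsv"))
    rows <- man[man$split == "test", , drop = FALSE]
    images <- file.path(config$run_dir, "data", rows$image_path)
  }
  if (is.null(out_dir)) out_dir <- file.path(config$run_dir, "predictions")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pre <- preprocess_config_from(config)
  post <- postprocess_config_from(config)
  rows <- lapply(images, function(ip) {
    img <- normalize_grayscale(read_image(ip), pre)
    prob <- predict_probmap(model, img)
    mask <- postprocess_probmap(prob, post)
    base <- tools::file_path_sans_ext(basename(ip))
    pp <- file.path(out_dir, paste0(base, "_prob.tif"))
    mp <- file.path(out_dir, paste0(base, "_mask.tif"))
    write_prob_map(prob, pp)
    write_label_map(mask, mp)
    data.frame(image = ip, prob_path = pp, mask_path = mp,
               n_instances = n_instances(mask), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!quiet) message(sprintf("predicted %d images -> %s", nrow(out), out_dir))
  invisible(out)
}

#' Score predicted masks against ground truth
#'
#' Matches prediction and truth label maps, computes the full
#' [evaluate_masks()] report per image plus an unweighted mean row, and
#' writes `metrics.csv`.
#'
#' @param pred_paths,truth_paths Equal-length vectors of label-map paths,
#'   matched positionally (or by name when `by_name = TRUE`).
#' @param out_csv Optional output CSV path.
#' @param percent Report metrics on the 0-100 scale.
#' @param by_name Match files by basename instead of position.
#' @return data.frame of per-image rows plus a `"mean"` row.
#' @export
cmd_evaluate <- function(pred_paths, truth_paths, out_csv = NULL,
                         percent = FALSE, by_name = FALSE) {
  if (by_name) {
    truth_paths <- truth_paths[match(basename(pred_paths), basename(truth_paths))]
    if (anyNA(truth_paths)) err_manifest("prediction files without matching truth files")
  }
  if (length(pred_paths) != length(truth_paths) || !length(pred_paths))
    err_manifest("prediction and truth lists must be non-empty and equal length")
  rows <- lapply(seq_along(pred_paths), function(i) {
    rep <- evaluate_masks(read_label_map(pred_paths[i]), read_label_map(truth_paths[i]))
    cbind(data.frame(image = basename(pred_paths[i]), stringsAsFactors = FALSE),
          as.data.frame(rep))
  })
  df <- do.call(rbind, rows)
  mean_row <- data.frame(image = "mean", t(colMeans(df[, -1, drop = FALSE])))
  names(mean_row) <- names(df)
  df <- rbind(df, mean_row)
  if (percent) {
    for (cl in c("dice1", "dice2", "aji", "dq", "sq", "pq")) df[[cl]] <- 100 * df[[cl]]
  }
  if (!is.null(out_csv))
    utils::write.table(df, out_csv, sep = ",", row.names = FALSE, quote = FALSE)
  df
}

scale_for_display <- function(m) {
  rg <- range(m)
  if (diff(rg) == 0) list(img = m * 0, range = rg)
  else list(img = (m - rg[1]) / diff(rg), range = rg)
}

#' Visualize feature maps or attention-gate coefficients
#'
#' Writes one PNG grid per requested convolution block (the five
#' canonical depths: first block, before the first up-sampling, middle,
#' before the second up-sampling, last block) or one PNG per attention
#' gate. Maps are min-max scaled for display and the original range is
#' recorded in the returned table.
#'
#' @param checkpoint Path to a model checkpoint.
#' @param image_path Path to the input image.
#' @param what `"features"` or `"attention"`.
#' @param out_dir Output directory for the PNG files.
#' @param pre Optional [preprocess_config()] used for normalisation.
#' @return data.frame describing the written files (layer, file, min,
#'   max).
#' @export
cmd_visualize <- function(checkpoint, image_path, what = c("features", "attention"),
                          out_dir = ".", pre = preprocess_config()) {
  what <- match.arg(what)
  model <- load_checkpoint(checkpoint)
  img <- normalize_grayscale(read_image(image_path), pre)
  x <- unclass(img); attributes(x) <- list(dim = dim(x))
  if (any(dim(x) %% 8L != 0L)) {
    H <- nrow(x); W <- ncol(x)
    Hp <- 8L * ((H + 7L) %/% 8L); Wp <- 8L * ((W + 7L) %/% 8L)
    ri <- c(seq_len(H), rev(seq_len(H))[seq_len(Hp - H)])
    ci <- c(seq_len(W), rev(seq_len(W))[seq_len(Wp - W)])
    x <- x[ri, ci, drop = FALSE]
  }
  fw <- net_forward(model, x, training = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  if (what == "attention") {
    if (!length(fw$coefs))
      err_unknown_layer(sprintf("model variant '%s' has no attention gates", model$variant))
    for (nm in names(fw$coefs)) {
      co <- tp_value(fw$tape, fw$coefs[[nm]])[, , 1]
      sc <- scale_for_display(co)
      fp <- file.path(out_dir, sprintf("attention_%s.png", nm))
      png::writePNG(sc$img, fp)
      rows[[nm]] <- data.frame(layer = nm, file = fp,
                               min = sc$range[1], max = sc$range[2])
    }
  } else {
    canon <- if (model$variant %in% c("asw", "sw"))
      c("c0", "c2", "c3", "c4", "c6") else c("e0", "e2", "bott", "d2", "d0")
    for (nm in canon) {
      feat <- tp_value(fw$tape, fw$blocks[[nm]])
      nc <- dim(feat)[3]
      ncol_g <- ceiling(sqrt(nc))
      nrow_g <- ceiling(nc / ncol_g)
      grid <- matrix(0, nrow_g * dim(feat)[1], ncol_g * dim(feat)[2])
      rg <- range(feat)
      for (ch in seq_len(nc)) {
        r0 <- ((ch - 1) %/% ncol_g) * dim(feat)[1]
        c0 <- ((ch - 1) %% ncol_g) * dim(feat)[2]
        sl <- feat[, , ch]
        grid[r0 + seq_len(dim(feat)[1]), c0 + seq_len(dim(feat)[2])] <-
          if (diff(rg) == 0) 0 else (sl - rg[1]) / diff(rg)
      }
      fp <- file.path(out_dir, sprintf("features_%s.png", nm))
      png::writePNG(grid, fp)
      rows[[nm]] <- data.frame(layer = nm, file = fp, min = rg[1], max = rg[2])
    }
  }
  do.call(rbind, rows)
}
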