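# Synthetic fluorescence-microscopy simulator: deformed elliptical nuclei
# with radial intensity falloff on a flat background, Gaussian read noise
# (optional Poisson shot noise), controllable density, clumping and SNR.
# Emulates the two benchmark regimes the framework targets: a clean,
# dense single-DNA-channel set and a low-SNR set.

#' Configuration for the synthetic nucleus simulator
#'
#' @param image_height,image_width Canvas size in pixels.
#' @param n_nuclei Number of nuclei to place (overridden by `density_mode`).
#' @param density_mode Optional preset `"low"`, `"medium"` or `"high"`;
#'   chooses `n_nuclei` from the target foreground coverage (5%, 12%, 25%)
#'   and the mean nucleus area.
#' @param radius_range Min/max semi-minor axis in pixels (min >= 2).
#' @param eccentricity_range Axis-ratio range (1 = circle).
#' @param clump_fraction Fraction of nuclei placed touching an existing
#'   neighbour (labels stay distinct, pixel sets disjoint).
#' @param snr Target signal-to-noise ratio: mean in-nucleus signal above
#'   background divided by the noise standard deviation.
#' @param background_level Background intensity (camera counts).
#' @param amplitude Peak nucleus signal above background (camera counts).
#' @param shot_noise Add Poisson shot noise on top of Gaussian read noise.
#' @param rng_seed Integer seed; the whole sample is deterministic in it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(image_height = 256L, image_width = 256L,
                         n_nuclei = 12L, density_mode = NULL,
                         radius_range = c(10, 18),
                         eccentricity_range = c(1, 1.8),
                         clump_fraction = 0.15,
                         snr = 8, background_level = 500,
                         amplitude = 3000, shot_noise = FALSE,
                         rng_seed = 1L) {
  stopifnot(image_height >= 1, image_width >= 1, n_nuclei >= 0, snr > 0,
            radius_range[1] >= 2, radius_range[2] >= radius_range[1],
            eccentricity_range[1] >= 1, clump_fraction >= 0, clump_fraction <= 1)
  if (!is.null(density_mode)) {
    density_mode <- match.arg(density_mode, c("low", "medium", "high"))
    coverage <- c(low = 0.05, medium = 0.12, high = 0.25)[[density_mode]]
    mean_area <- pi * mean(radius_range)^2 * mean(eccentricity_range)
    n_nuclei <- max(1L, as.integer(round(coverage * image_height * image_width / mean_area)))
  }
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 n_nuclei = as.integer(n_nuclei), density_mode = density_mode,
                 radius_range = radius_range,
                 eccentricity_range = eccentricity_range,
                 clump_fraction = clump_fraction, snr = snr,
                 background_level = background_level, amplitude = amplitude,
                 shot_noise = shot_noise, rng_seed = as.integer(rng_seed)),
            class = "synth_config")
}

#' Simulator preset mirroring a benchmark regime
#'
#' `"bbbc039-like"` emulates a clean high-throughput DNA-channel screen
#' (normal SNR, moderate density, touching nuclei); `"low-snr"` emulates
#' the noisy regime with the same geometry at SNR 2.
#'
#' @param name `"bbbc039-like"` or `"low-snr"`.
#' @param ... Overrides passed on to [synth_config()].
#' @return A `synth_config`.
#' @export
synth_preset <- function(name = c("bbbc039-like", "low-snr"), ...) {
  name <- match.arg(name)
  base <- list(image_height = 256L, image_width = 256L, density_mode = "medium",
               clump_fraction = 0.25, snr = if (name == "low-snr") 2 else 10)
  args <- utils::modifyList(base, list(...))
  do.call(synth_config, args)
}

# Run code under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Rasterize one wobbled ellipse. Returns linear pixel indices (within the
# canvas) and the normalised radial coordinate s in [0, 1] of each pixel.
rasterize_nucleus <- function(cy, cx, r0, ecc, theta0, wob_a, wob_phi, H, W) {
  rmax <- r0 * ecc * (1 + sum(abs(wob_a))) + 1
  rows <- max(1L, floor(cy - rmax)):min(H, ceiling(cy + rmax))
  cols <- max(1L, floor(cx - rmax)):min(W, ceiling(cx + rmax))
  if (!length(rows) || !length(cols)) return(list(idx = integer(), s = numeric()))
  dy <- rep(rows - cy, times = length(cols))
  dx <- rep(cols - cx, each = length(rows))
  u <- cos(theta0) * dx + sin(theta0) * dy     # along the major axis
  v <- -sin(theta0) * dx + cos(theta0) * dy
  s <- sqrt((u / (r0 * ecc))^2 + (v / r0)^2)
  ang <- atan2(v, u)
  sb <- 1 + Reduce(`+`, lapply(seq_along(wob_a), function(k)
    wob_a[k] * cos((k + 1) * ang + wob_phi[k])), accumulate = FALSE)
  inside <- s <= sb & sb > 0
  lin <- rep((cols - 1L) * H, each = length(rows)) + rep(rows, times = length(cols))
  list(idx = lin[inside], s = pmin(s[inside] / pmax(sb[inside], 1e-9), 1))
}

# 8-neighbourhood dilation of a set of linear indices (clipped to canvas).
dilate_idx <- function(idx, H, W) {
  r <- (idx - 1L) %% H + 1L
  c <- (idx - 1L) %/% H + 1L
  out <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    rr <- r + dr; cc <- c + dc
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    out <- c(out, (cc[ok] - 1L) * H + rr[ok])
  }
  unique(out)
}

#' Generate one synthetic nucleus image with ground truth
#'
#' Nuclei are randomly oriented ellipses whose boundary is perturbed by a
#' low-order Fourier wobble, filled with a radial intensity falloff and
#' per-nucleus brightness variation. A `clump_fraction` subset is placed
#' touching an existing nucleus (adjacent pixels, distinct labels, no
#' shared pixels). Additive Gaussian noise is scaled so that the mean
#' in-nucleus signal over the noise standard deviation equals the target
#' SNR; Poisson shot noise can be layered on top. Deterministic in
#' `config$rng_seed`. If a nucleus cannot be placed within the retry
#' budget the sample is emitted with fewer nuclei and `placement_warning`
#' set.
#'
#' @param config A [synth_config()].
#' @return A `synth_sample`: list with `image` ([gray_image()]), `truth`
#'   ([instance_mask()]), `config`, `n_placed`, `placement_warning`.
#' @export
generate_nuclei_image <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  H <- config$image_height; W <- config$image_width
  with_seed(config$rng_seed, {
    labels <- matrix(0L, H, W)
    signal <- matrix(0, H, W)
    n <- config$n_nuclei
    clumped <- rep(FALSE, n)
    if (n > 1 && config$clump_fraction > 0) {
      k <- min(n - 1L, round(config$clump_fraction * n))
      if (k > 0) clumped[sample(2:n, k)] <- TRUE
    }
    centers <- matrix(NA_real_, n, 2)
    placed <- 0L; warn <- FALSE
    for (i in seq_len(n)) {
      r0 <- runif(1, config$radius_range[1], config$radius_range[2])
      ecc <- runif(1, config$eccentricity_range[1], config$eccentricity_range[2])
      theta0 <- runif(1, 0, pi)
      wob_a <- pmax(pmin(rnorm(3, 0, 0.03), 0.09), -0.09)
      wob_phi <- runif(3, 0, 2 * pi)
      bright <- runif(1, 0.8, 1.2)
      margin <- r0 * ecc * 1.2 + 1
      ok <- FALSE
      if (clumped[i] && placed > 0) {
        cand <- seq_len(i - 1L)[!is.na(centers[seq_len(i - 1L), 1])]
        partner <- cand[sample.int(length(cand), 1L)]
        phi <- runif(1, 0, 2 * pi)
        for (d in seq(from = 2 * max(config$radius_range) * max(config$eccentricity_range) + 2,
                      to = 2, by = -1)) {
          cy <- centers[partner, 1] + d * sin(phi)
          cx <- centers[partner, 2] + d * cos(phi)
          if (cy < 2 || cy > H - 1 || cx < 2 || cx > W - 1) next
          ras <- rasterize_nucleus(cy, cx, r0, ecc, theta0, wob_a, wob_phi, H, W)
          if (!length(ras$idx)) next
          if (any(labels[ras$idx] > 0L)) break       # stepped too far: previous d touched
          touching <- any(labels[dilate_idx(ras$idx, H, W)] > 0L)
          if (touching) { ok <- TRUE; break }
          keep <- ras                                 # remember nearest non-touching
        }
        if (ok) keep <- ras
      }
      if (!ok) {                                      # free placement, non-touching
        for (try in seq_len(200L)) {
          cy <- runif(1, margin, H - margin + 1)
          cx <- runif(1, margin, W - margin + 1)
          if (cy < 1 || cx < 1 || cy > H || cx > W) next
          ras <- rasterize_nucleus(cy, cx, r0, ecc, theta0, wob_a, wob_phi, H, W)
          if (!length(ras$idx)) next
          if (!any(labels[dilate_idx(ras$idx, H, W)] > 0L)) { ok <- TRUE; keep <- ras; break }
        }
      }
      if (!ok) { warn <- TRUE; next }
      placed <- placed + 1L
      free <- keep$idx[labels[keep$idx] == 0L]
      sfree <- keep$s[labels[keep$idx] == 0L]
      labels[free] <- placed
      signal[free] <- bright * (1 - 0.3 * sfree^2)
      centers[i, ] <- c(cy, cx)
    }
    sig <- config$amplitude * signal
    mean_sig <- if (placed > 0) mean(sig[labels > 0L]) else config$amplitude * 0.8
    sigma <- mean_sig / config$snr
    px <- config$background_level + sig + rnorm(H * W, 0, sigma)
    if (config$shot_noise) {
      lam <- pmax(config$background_level + sig, 0)
      px <- px + (rpois(H * W, lam) - lam)
    }
    # shift (rather than clip) any negative tail so the noise statistics,
    # and hence the realised SNR, survive the conversion to counts
    if (min(px) < 0) px <- px - min(px)
    px <- matrix(pmin(round(px), 65535), H, W)
    structure(list(image = gray_image(px, "uint16"),
                   truth = instance_mask(labels),
                   config = config, n_placed = placed,
                   placement_warning = warn),
              class = "synth_sample")
  })
}

#' @export
print.synth_sample <- function(x, ...) {
  cat(sprintf("<synth_sample %d x %d, %d nuclei, snr %.2g%s>\n",
              nrow(x$image), ncol(x$image), x$n_placed, x$config$snr,
              if (x$placement_warning) ", placement warning" else ""))
  invisible(x)
}

#' Measure the realised signal-to-noise ratio of a synthetic sample
#'
#' Mean in-nucleus signal above the background mean, divided by the
#' background standard deviation.
#'
#' @param sample A `synth_sample`.
#' @return Scalar SNR estimate.
#' @export
measure_snr <- function(sample) {
  img <- as.vector(unclass(sample$image))
  fg <- as.vector(unclass(sample$truth)) > 0L
  (mean(img[fg]) - mean(img[!fg])) / stats::sd(img[!fg])
}

#' Generate a train/validation/test dataset on disk
#'
#' Writes image/mask TIFF pairs into `train/`, `val/` and `test/`
#' subdirectories of `out_dir` plus a tab-separated manifest
#' (`manifest.tsv`, columns: split, image_path, mask_path, seed). Each
#' sample's seed is derived deterministically from `config$rng_seed` and
#' the sample index, so the whole tree is reproducible.
#'
#' @param config A [synth_config()] used as the template for every sample.
#' @param n_train,n_val,n_test Split sizes (>= 0). The benchmark partition
#'   this mirrors is 100/50/50.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest as a data.frame.
#' @export
generate_dataset <- function(config, n_train = 100L, n_val = 50L, n_test = 50L,
                             out_dir) {
  stopifnot(n_train >= 0, n_val >= 0, n_test >= 0)
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) err_io(sprintf("cannot write to '%s'", out_dir))
  splits <- rep(c("train", "val", "test"), times = c(n_train, n_val, n_test))
  rows <- vector("list", length(splits))
  for (s in unique(splits)) dir.create(file.path(out_dir, s), showWarnings = FALSE)
  for (i in seq_along(splits)) {
    seed_i <- derive_seed(config$rng_seed, i)
    cfg <- config; cfg$rng_seed <- seed_i
    smp <- generate_nuclei_image(cfg)
    ip <- file.path(splits[i], sprintf("image_%04d.tif", i))
    mp <- file.path(splits[i], sprintf("mask_%04d.tif", i))
    write_image(smp$image, file.path(out_dir, ip))
    write_label_map(smp$truth, file.path(out_dir, mp))
    rows[[i]] <- data.frame(split = splits[i], image_path = ip,
                            mask_path = mp, seed = seed_i,
                            stringsAsFactors = FALSE)
  }
  manifest <- if (length(rows)) do.call(rbind, rows)
  else data.frame(split = character(), image_path = character(),
                  mask_path = character(), seed = integer())
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a dataset manifest
#' @param path Path to a `manifest.tsv` written by [generate_dataset()].
#' @return data.frame with columns split, image_path, mask_path, seed.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) err_not_found(sprintf("manifest '%s' does not exist", path))
  utils::read.delim(path, stringsAsFactors = FALSE)
}
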