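# aswnet

Instance segmentation of cell nuclei in single-channel fluorescence
microscopy images, in R.

Automated measurement of nuclear morphology — counts, areas, shapes —
requires each nucleus to be delineated individually, including nuclei
that touch or clump. `aswnet` implements a complete framework for this
task:

1. **Three-class semantic prediction.** Every pixel is classified as
   background, nucleus *interior*, or nucleus *boundary* by ASW-Net, a
   lightweight cascade ("W"-shaped) encoder–decoder with three
   down-sampling stages, three up-sampling stages and an additive
   attention gate on every up-sampling skip connection. The gate-free
   sibling (SW-Net) and a plain 3-scale U-Net are included as ablation
   baselines. The networks — forward pass, exact backpropagation and
   RMSProp training with early stopping — are implemented natively on a
   small reverse-mode tape over vectorised array operations, so
   everything runs on one CPU with no external deep-learning runtime.
2. **Interior-expansion post-processing.** Pixels with interior
   probability > 0.5 seed the nuclei; each seed then grows one pixel per
   iteration, ascending the boundary-probability field until the ridge
   crest, discarding the crest pixels, and leaving pixels contested by
   two nuclei unassigned — touching nuclei come out as disjoint labels
   separated by a one-pixel gap. Marker-based watershed and plain
   threshold labeling are provided for ablations.
3. **Evaluation metrics.** Pixel Dice (DICE1), object-level ensemble
   Dice (DICE2), Aggregated Jaccard Index (AJI), and Panoptic Quality
   with its factors (PQ = DQ × SQ), plus per-nucleus areas and the
   nucleus-area Pearson correlation used as a downstream consistency
   check:

   ```
   DQ = TP / (TP + FP/2 + FN/2),   SQ = mean IoU over matches (IoU > 0.5)
   AJI = Σ matched |G ∩ P| / (Σ matched |G ∪ P| + Σ unmatched areas)
   ```

4. **A synthetic fluorescence simulator** (`generate_nuclei_image()`,
   `generate_dataset()`) producing wobbled elliptical nuclei with
   radial intensity falloff, controllable density, clumping fraction and
   signal-to-noise ratio, plus ground-truth instance masks — so the
   whole pipeline is testable end to end without downloading data.

Who is it for: image-analysis researchers who want an auditable,
dependency-light reference implementation of three-class nucleus
segmentation with attention gating, and method developers who need
oracle-checked AJI/PQ scoring or a controllable nucleus simulator.

## Worked example

```r
library(aswnet)

# simulate a small image with clumped nuclei and ground truth
s <- generate_nuclei_image(synth_config(image_height = 128, image_width = 128,
                                        n_nuclei = 8, radius_range = c(6, 12),
                                        clump_fraction = 0.25, snr = 8,
                                        rng_seed = 7))
s
#> <synth_sample 128 x 128, 8 nuclei, snr 8>

# an untrained tiny ASW-Net already has the right output contract
model <- build_asw_net(network_config(base_filters = 4))
model
#> <ASW model: base_filters=4, kernel=3, attention gates, 13585 parameters>

# decode an ideal probability map (built from the truth) to instances
pm  <- ideal_prob_map(s$truth, boundary_width = 2)
out <- interior_expansion(pm)
evaluate_masks(out, s$truth)
#> DICE1 0.9997  DICE2 0.9997  AJI 0.9994  DQ 1.0000  SQ 0.9988  PQ 0.9988 (TP 8 FP 0 FN 0)

# the thresholding baseline forfeits the boundary band
evaluate_masks(threshold_labeling(pm), s$truth)
#> DICE1 0.7554  DICE2 0.7554  AJI 0.6069  DQ 0.6250  SQ 0.6422  PQ 0.4014 (TP 5 FP 3 FN 3)
```

The AJI gap between the two decoders (+0.39 here on an ideal map) is the
reason interior expansion exists: thresholding keeps only the interior
class, so every nucleus loses its boundary band.

Training on a synthetic dataset and predicting is a four-call pipeline
(see `?pipeline_config` for the YAML-configurable version, and
`inst/cli/aswnet.R` for the shell front end with `generate`, `train`,
`predict`, `evaluate` and `visualize` subcommands):

```r
cfg <- pipeline_config(run_dir = "run")
cfg$synth <- list(preset = "bbbc039-like", image_height = 128, image_width = 128,
                  n_nuclei = 8, radius_range = c(6, 12), clump_fraction = 0.25,
                  snr = 8, n_train = 40, n_val = 10, n_test = 10, rng_seed = 11)
cfg$model$base_filters <- 4
cfg$train$max_epochs <- 30
cfg$train$learning_rate <- 2e-3
cmd_generate(cfg)
cmd_train(cfg)          # ~5 minutes on one CPU
preds <- cmd_predict(cfg)
man <- read_manifest("run/data/manifest.tsv")
cmd_evaluate(preds$mask_path,
             file.path("run/data", man$mask_path[man$split == "test"]))
```

On this configuration the trained network reaches a mean test AJI around
0.7 with nucleus-area correlation above 0.95 (exact values vary with the
seed); `cmd_visualize()` writes feature-map grids and the three
attention-gate coefficient maps for any checkpoint.

## Scope notes

TIFF (8/16-bit integer, 32-bit) and PNG (8/16-bit) images are supported;
instance label maps are 16-bit TIFF with a two-page fallback above
65535. Images of arbitrary size are handled by reflect-padding to the
next multiple of 8 internally. Out of scope: 3-D stacks, OME-TIFF
metadata, multi-channel stains, GPU execution, and pretrained weights —
models are small enough to train where they are used.
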