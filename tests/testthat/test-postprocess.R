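prob_from_classes <- function(cls) {
  a <- array(0, c(dim(cls), 3))
  for (k in 0:2) a[, , k + 1] <- (cls == k) * 1
  prob_map(a)
}

test_that("seeding uses a strict threshold and a flood-fill component oracle agrees", {
  a <- array(0, c(12, 12, 3)); a[, , 1] <- 0.6; a[, , 2] <- 0.4
  expect_equal(n_instances(seed_from_interior(prob_map(a))), 0L)

  a[, , 1] <- 0.5; a[, , 2] <- 0.5          # exactly at threshold: not a seed
  expect_equal(n_instances(seed_from_interior(prob_map(a))), 0L)

  b <- array(0, c(20, 20, 3)); b[, , 1] <- 1
  for (rc in list(3:6, 12:16)) {
    b[rc, rc, 2] <- 0.9; b[rc, rc, 1] <- 0.1
  }
  seeds <- seed_from_interior(prob_map(b))
  expect_equal(n_instances(seeds), 2L)
  expect_equal(oracle_component_count(unclass(seeds) > 0L, 8L), 2L)
})

test_that("expansion is inert when background dominates everywhere outside the seeds", {
  a <- array(0, c(16, 16, 3)); a[, , 1] <- 1
  a[5:8, 5:8, 2] <- 1; a[5:8, 5:8, 1] <- 0
  pm <- prob_map(a)
  seeds <- seed_from_interior(pm)
  out <- interior_expansion(pm, seeds)
  expect_identical(unclass(out)[, ], unclass(seeds)[, ])
})

test_that("an ideal disk is recovered with IoU >= 0.9", {
  truth <- disk_mask(40, 40, 20, 20, 12)
  pm <- ideal_prob_map(truth, boundary_width = 2L)
  out <- interior_expansion(pm)
  expect_equal(n_instances(out), 1L)
  inter <- sum(out > 0L & truth > 0L)
  expect_gte(inter / sum(out > 0L | truth > 0L), 0.9)
})

test_that("touching nuclei stay disjoint with an unassigned contested ridge", {
  # explicit symmetric fixture: two interior slabs flanking a 1-px
  # boundary ridge, seeds equidistant from the ridge
  a <- array(0, c(20, 21, 3)); a[, , 1] <- 1
  a[5:16, 4:9, 2] <- 1; a[5:16, 4:9, 1] <- 0      # left interior
  a[5:16, 13:18, 2] <- 1; a[5:16, 13:18, 1] <- 0  # right interior
  a[5:16, 10:12, 3] <- 1; a[5:16, 10:12, 1] <- 0  # shared boundary band
  pm <- prob_map(a)
  out <- interior_expansion(pm)
  m <- unclass(out)
  expect_equal(n_instances(out), 2L)
  # both labels advance into the band but the contested middle column
  # stays unassigned, leaving a one-pixel separation
  expect_true(all(m[5:16, 11] == 0L))
  expect_true(all(m[5:16, 10] != m[5:16, 12]))
  left <- m[8, 4]; right <- m[8, 18]
  expect_true(left != right && left > 0L && right > 0L)

  # the same holds for touching wobbled disks: disjoint labels, no leakage
  truth <- touching_disks()
  out2 <- interior_expansion(ideal_prob_map(truth, boundary_width = 2L))
  m2 <- unclass(out2)
  expect_equal(n_instances(out2), 2L)
  for (lb in 1:2) {
    other <- unclass(truth) == (3L - lb)
    expect_lt(sum(m2 == lb & other) / sum(m2 == lb), 0.05)
  }
})

test_that("watershed and threshold baselines behave on ideal maps", {
  # single blob: one instance covering the non-background region
  a <- array(0, c(24, 24, 3)); a[, , 1] <- 1
  a[8:16, 8:16, 2] <- 0.95; a[8:16, 8:16, 1] <- 0.05
  a[7, 8:16, 3] <- 0.9; a[7, 8:16, 1] <- 0.1
  pm <- prob_map(a)
  ws <- watershed_postprocess(pm)
  expect_equal(n_instances(ws), 1L)
  nonbg <- a[, , 1] < pmax(a[, , 2], a[, , 3])
  expect_true(all(unclass(ws)[nonbg] > 0L))

  # empty seeds: empty output
  empty <- array(0, c(8, 8, 3)); empty[, , 1] <- 1
  expect_equal(n_instances(watershed_postprocess(prob_map(empty))), 0L)
  expect_equal(n_instances(threshold_labeling(prob_map(empty))), 0L)

  # two touching nuclei: both methods separate them
  truth <- touching_disks()
  ipm <- ideal_prob_map(truth, 2L)
  expect_equal(n_instances(watershed_postprocess(ipm)), 2L)
  thr <- threshold_labeling(ipm)
  expect_equal(n_instances(thr), 2L)
  # threshold keeps only argmax-interior pixels
  expect_identical(unclass(thr) > 0L, ipm[, , 2] > 0.5)
})

test_that("all decoders output disjoint connected instances on simulated nuclei", {
  set.seed(19)
  for (i in 1:5) {
    s <- generate_nuclei_image(synth_config(image_height = 128L, image_width = 128L,
                                            n_nuclei = 10L, radius_range = c(6, 11),
                                            clump_fraction = 0.3, rng_seed = 70L + i))
    pm <- ideal_prob_map(s$truth, 2L)
    for (method in c("interior_expansion", "watershed", "threshold")) {
      out <- postprocess_probmap(pm, postprocess_config(method = method))
      m <- unclass(out)
      for (lb in setdiff(unique(as.vector(m)), 0L))
        expect_equal(oracle_component_count(m == lb, 8L), 1L)
    }
    # expansion recovers at least as well as thresholding
    expect_gte(aji(interior_expansion(pm), s$truth),
               aji(threshold_labeling(pm), s$truth))
  }
})

test_that("expansion terminates within the iteration cap on random probability fields", {
  set.seed(23)
  for (i in 1:5) {
    a <- array(runif(32 * 32 * 3), c(32, 32, 3))
    s <- a[, , 1] + a[, , 2] + a[, , 3]
    for (k in 1:3) a[, , k] <- a[, , k] / s
    pm <- prob_map(a)
    out <- interior_expansion(pm, config = postprocess_config(max_iterations = 64L))
    m <- unclass(out)
    seeds <- seed_from_interior(pm)
    # every output pixel is a seed pixel or was claimed during growth, and
    # instances stay disjoint by construction of the label map
    expect_true(all(m[unclass(seeds) > 0L] == unclass(seeds)[unclass(seeds) > 0L]))
  }
})

test_that("adding a distant seed never changes other instances", {
  truth <- disk_mask(48, 48, 14, 14, 8)
  pm <- ideal_prob_map(truth, 2L)
  seeds <- seed_from_interior(pm)
  out1 <- interior_expansion(pm, seeds)
  s2 <- unclass(seeds)
  s2[40:42, 40:42] <- max(s2) + 1L          # far-away artificial seed
  out2 <- interior_expansion(pm, instance_mask(s2))
  keep <- unclass(out1) > 0L
  expect_identical(unclass(out2)[keep], unclass(out1)[keep])
})
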