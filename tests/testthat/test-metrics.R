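test_that("identity, disjoint and empty masks hit the metric boundary values", {
  m <- random_mask(24, 24, 4)
  expect_equal(dice1(m, m), 1)
  expect_equal(dice2(m, m), 1)
  expect_equal(aji(m, m), 1)
  pq <- panoptic_quality(m, m)
  expect_equal(c(pq$dq, pq$sq, pq$pq), c(1, 1, 1))
  expect_equal(pq$tp, n_instances(m))

  a <- matrix(0L, 8, 8); a[1:2, 1:2] <- 1L
  b <- matrix(0L, 8, 8); b[6:7, 6:7] <- 1L
  expect_equal(dice1(instance_mask(a), instance_mask(b)), 0)

  empty <- instance_mask(matrix(0L, 8, 8))
  expect_equal(dice1(empty, empty), 1)
  expect_equal(dice2(empty, empty), 1)
  expect_equal(aji(empty, empty), 1)
  one <- instance_mask(a)
  expect_equal(dice2(empty, one), 0)
  rep <- evaluate_masks(empty, one)
  expect_equal(c(rep$dice1, rep$dice2, rep$aji, rep$pq), c(0, 0, 0, 0))
})

test_that("the shifted-square toy reproduces its hand-derived values", {
  toy <- toy_shifted_squares()
  expect_equal(dice1(toy$pred, toy$truth), 0.5)
  expect_equal(dice2(toy$pred, toy$truth), 0.5)   # single objects: equals dice1
  expect_equal(aji(toy$pred, toy$truth), 1 / 3)
  pq <- panoptic_quality(toy$pred, toy$truth)     # IoU = 1/3 < 0.5
  expect_equal(pq$tp, 0L)
  expect_equal(pq$fp, 1L)
  expect_equal(pq$fn, 1L)
  expect_equal(pq$dq, 0)
  expect_equal(pq$pq, 0)
})

test_that("an exact match plus a spurious prediction gives DQ = 2/3", {
  truth <- matrix(0L, 12, 12); truth[2:4, 2:4] <- 1L
  pred <- truth; pred[8:10, 8:10] <- 2L
  pq <- panoptic_quality(instance_mask(pred), instance_mask(truth))
  expect_equal(pq$tp, 1L); expect_equal(pq$fp, 1L); expect_equal(pq$fn, 0L)
  expect_equal(pq$dq, 1 / (1 + 0.5))
  expect_equal(pq$sq, 1)
  expect_equal(pq$pq, 2 / 3)
})

test_that("metrics agree with brute-force oracles on random mask pairs", {
  set.seed(101)
  for (i in 1:200) {
    pr <- random_mask_pair(32, 32, 5)
    expect_equal(dice1(pr$pred, pr$truth), oracle_dice1(unclass(pr$pred), unclass(pr$truth)),
                 tolerance = 1e-12)
    expect_equal(dice2(pr$pred, pr$truth), oracle_dice2(unclass(pr$pred), unclass(pr$truth)),
                 tolerance = 1e-12)
    expect_equal(aji(pr$pred, pr$truth), oracle_aji(unclass(pr$pred), unclass(pr$truth)),
                 tolerance = 1e-12)
    pq <- panoptic_quality(pr$pred, pr$truth)
    opq <- oracle_pq(unclass(pr$pred), unclass(pr$truth))
    expect_equal(pq$pq, opq$pq, tolerance = 1e-12)
    expect_equal(pq$tp, opq$tp)
  }
})

test_that("metrics are invariant under instance-label permutation and AJI <= DICE1", {
  set.seed(55)
  # permutation invariance on irregular simulator masks (generic inputs,
  # where best-overlap matches are unique)
  for (i in 1:5) {
    s <- generate_nuclei_image(synth_config(image_height = 96L, image_width = 96L,
                                            n_nuclei = 7L, radius_range = c(5, 9),
                                            clump_fraction = 0.3, rng_seed = 500L + i))
    pred <- interior_expansion(ideal_prob_map(s$truth, 2L))
    m <- unclass(pred)
    labs <- setdiff(sort(unique(as.vector(m))), 0L)
    perm <- sample(labs)
    m2 <- m
    for (j in seq_along(labs)) m2[m == labs[j]] <- perm[j] + 1000L
    shuffled <- instance_mask(m2)
    expect_equal(aji(shuffled, s$truth), aji(pred, s$truth))
    expect_equal(dice2(shuffled, s$truth), dice2(pred, s$truth))
    expect_equal(panoptic_quality(shuffled, s$truth)$pq,
                 panoptic_quality(pred, s$truth)$pq)
  }
  # aggregated Jaccard never exceeds aggregated Dice on the same pair
  for (i in 1:50) {
    pr <- random_mask_pair(24, 24, 4)
    expect_lte(aji(pr$pred, pr$truth), dice1(pr$pred, pr$truth) + 1e-12)
  }
})

test_that("PQ matching above IoU 0.5 is one-to-one", {
  set.seed(77)
  for (i in 1:30) {
    pr <- random_mask_pair(24, 24, 4)
    tab <- panoptic_quality(pr$pred, pr$truth)$match_table$pairs
    expect_equal(anyDuplicated(tab$gt), 0L)
    expect_equal(anyDuplicated(tab$pred), 0L)
  }
})

test_that("evaluate_masks composes the individual metrics", {
  toy <- toy_shifted_squares()
  rep <- evaluate_masks(toy$pred, toy$truth)
  expect_equal(rep$dice1, dice1(toy$pred, toy$truth))
  expect_equal(rep$dice2, dice2(toy$pred, toy$truth))
  expect_equal(rep$aji, aji(toy$pred, toy$truth))
  expect_equal(rep$pq, panoptic_quality(toy$pred, toy$truth)$pq)
  expect_error(dice1(toy$pred, instance_mask(matrix(0L, 3, 3))),
               class = "aswnet_shape_error")
})

test_that("nucleus areas count pixels and conserve the foreground", {
  m <- matrix(0L, 10, 10); m[3:6, 3:6] <- 1L
  expect_equal(nucleus_areas(instance_mask(m)),
               data.frame(label = 1L, area = 16L))
  expect_equal(nrow(nucleus_areas(instance_mask(matrix(0L, 5, 5)))), 0L)
  set.seed(3)
  r <- random_mask(32, 32, 6)
  ar <- nucleus_areas(r)
  expect_equal(sum(ar$area), sum(unclass(r) > 0L))
})

test_that("area correlation matches the direct covariance formula", {
  truth <- matrix(0L, 40, 40)
  pred <- matrix(0L, 40, 40)
  sides <- c(2L, 4L, 6L, 8L)
  at <- c(1L, 10L, 19L, 29L)
  for (i in seq_along(sides)) {
    r <- at[i]
    truth[r:(r + sides[i] - 1L), r:(r + sides[i] - 1L)] <- i
    pred[r:(r + sides[i] - 1L), r:(r + sides[i] - 2L)] <- i   # one column shorter
  }
  ac <- area_correlation(instance_mask(pred), instance_mask(truth))
  ga <- sides^2; pa <- sides * (sides - 1L)
  r_oracle <- sum((ga - mean(ga)) * (pa - mean(pa))) /
    sqrt(sum((ga - mean(ga))^2) * sum((pa - mean(pa))^2))
  expect_equal(ac$pearson_r, r_oracle)
  expect_equal(nrow(ac$pairs), 4L)

  # identical masks: r = 1
  expect_equal(area_correlation(instance_mask(truth), instance_mask(truth))$pearson_r, 1)

  # fewer than 3 matched pairs errors
  small <- matrix(0L, 10, 10); small[2:3, 2:3] <- 1L
  expect_error(area_correlation(instance_mask(small), instance_mask(small)),
               class = "aswnet_insufficient_pairs")
})
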