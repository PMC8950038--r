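# Shared fixtures built in code: toy masks, random label-map pairs, and
# hand-constructed probability maps.

# The canonical worked toy: a 2x2 square and its copy shifted one pixel
# right (overlap 2, sizes 4 + 4).
toy_shifted_squares <- function() {
  truth <- matrix(0L, 6, 6); truth[2:3, 2:3] <- 1L
  pred <- matrix(0L, 6, 6); pred[2:3, 3:4] <- 1L
  list(pred = instance_mask(pred), truth = instance_mask(truth))
}

# Random label map: up to n_obj axis-aligned rectangles stamped in order
# (later stamps overwrite earlier ones, so labels stay disjoint).
random_mask <- function(H = 32L, W = 32L, n_obj = 5L) {
  m <- matrix(0L, H, W)
  k <- sample.int(n_obj + 1L, 1L) - 1L
  for (i in seq_len(k)) {
    h <- sample.int(min(8L, H - 2L), 1L) + 1L
    w <- sample.int(min(8L, W - 2L), 1L) + 1L
    r <- sample.int(H - h, 1L); c <- sample.int(W - w, 1L)
    m[r:(r + h - 1L), c:(c + w - 1L)] <- i
  }
  # drop labels fully overwritten
  labs <- setdiff(sort(unique(as.vector(m))), 0L)
  m2 <- matrix(0L, H, W)
  for (j in seq_along(labs)) m2[m == labs[j]] <- j
  instance_mask(m2)
}

# A paired prediction: the truth with objects jittered, occasionally
# dropped, plus occasional spurious objects.
random_mask_pair <- function(H = 32L, W = 32L, n_obj = 5L) {
  truth <- random_mask(H, W, n_obj)
  t <- unclass(truth)
  p <- matrix(0L, H, W)
  labs <- setdiff(sort(unique(as.vector(t))), 0L)
  nxt <- 0L
  for (lb in labs) {
    if (runif(1) < 0.15) next                       # missed object
    nxt <- nxt + 1L
    sel <- which(t == lb, arr.ind = TRUE)
    dr <- sample(-3:3, 1L); dc <- sample(-3:3, 1L)
    rr <- sel[, 1] + dr; cc <- sel[, 2] + dc
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    p[cbind(rr[ok], cc[ok])] <- nxt
  }
  if (runif(1) < 0.3) {                             # spurious object
    h <- sample.int(5L, 1L) + 1L; w <- sample.int(5L, 1L) + 1L
    r <- sample.int(H - h, 1L); c <- sample.int(W - w, 1L)
    p[r:(r + h - 1L), c:(c + w - 1L)] <- nxt + 1L
  }
  list(pred = instance_mask(p), truth = truth)
}

# Ideal one-hot probability map of a single filled disk.
disk_mask <- function(H, W, cy, cx, radius) {
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  instance_mask(((rr - cy)^2 + (cc - cx)^2 <= radius^2) * 1L)
}

# Two touching disks with distinct labels.
touching_disks <- function(H = 48L, W = 48L, radius = 9L) {
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  a <- (rr - H / 2)^2 + (cc - (W / 2 - radius))^2 <= radius^2
  b <- (rr - H / 2)^2 + (cc - (W / 2 + radius + 1))^2 <= radius^2
  m <- matrix(0L, H, W)
  m[a] <- 1L
  m[b & !a] <- 2L
  instance_mask(m)
}
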