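# Independent brute-force oracles for the instance metrics: plain loops
# over label pairs with direct pixel counting, no shared code with the
# package implementations.

oracle_labels <- function(m) setdiff(sort(unique(as.vector(m))), 0L)

oracle_dice1 <- function(pred, truth) {
  p <- as.vector(pred) > 0; g <- as.vector(truth) > 0
  if (!any(p) && !any(g)) return(1)
  2 * sum(p & g) / (sum(p) + sum(g))
}

oracle_dice2 <- function(pred, truth) {
  gl <- oracle_labels(truth); pl <- oracle_labels(pred)
  if (!length(gl) && !length(pl)) return(1)
  num <- 0; den <- 0
  for (g in gl) {
    gm <- truth == g
    best <- 0; best_p <- NA
    for (p in pl) {
      ov <- sum(gm & pred == p)
      if (ov > best) { best <- ov; best_p <- p }
    }
    if (best > 0) { num <- num + 2 * best; den <- den + sum(gm) + sum(pred == best_p) }
    else den <- den + sum(gm)
  }
  for (p in pl) {
    pm <- pred == p
    best <- 0; best_g <- NA
    for (g in gl) {
      ov <- sum(pm & truth == g)
      if (ov > best) { best <- ov; best_g <- g }
    }
    if (best > 0) { num <- num + 2 * best; den <- den + sum(pm) + sum(truth == best_g) }
    else den <- den + sum(pm)
  }
  num / den
}

oracle_aji <- function(pred, truth) {
  gl <- oracle_labels(truth); pl <- oracle_labels(pred)
  if (!length(gl) && !length(pl)) return(1)
  used <- setNames(rep(FALSE, length(pl)), pl)
  C <- 0; U <- 0
  for (g in gl) {
    gm <- truth == g
    best_iou <- -1; best_p <- NA; best_int <- 0; best_uni <- 0
    for (p in pl) {
      if (used[as.character(p)]) next
      pm <- pred == p
      int <- sum(gm & pm)
      if (int == 0) next
      uni <- sum(gm | pm)
      iou <- int / uni
      if (iou > best_iou + 1e-15 ||
          (abs(iou - best_iou) <= 1e-15 && (is.na(best_p) || p < best_p))) {
        best_iou <- iou; best_p <- p; best_int <- int; best_uni <- uni
      }
    }
    if (!is.na(best_p)) {
      C <- C + best_int; U <- U + best_uni
      used[as.character(best_p)] <- TRUE
    } else U <- U + sum(gm)
  }
  for (p in pl) if (!used[as.character(p)]) U <- U + sum(pred == p)
  if (U == 0) return(1)
  C / U
}

oracle_pq <- function(pred, truth) {
  gl <- oracle_labels(truth); pl <- oracle_labels(pred)
  if (!length(gl) && !length(pl)) return(list(dq = 1, sq = 1, pq = 1, tp = 0))
  ious <- c()
  tp <- 0
  for (g in gl) {
    gm <- truth == g
    for (p in pl) {
      pm <- pred == p
      int <- sum(gm & pm)
      if (int == 0) next
      iou <- int / sum(gm | pm)
      if (iou > 0.5) { tp <- tp + 1; ious <- c(ious, iou) }
    }
  }
  fp <- length(pl) - tp; fn <- length(gl) - tp
  dq <- tp / (tp + fp / 2 + fn / 2)
  sq <- if (tp > 0) mean(ious) else 0
  list(dq = dq, sq = sq, pq = dq * sq, tp = tp, fp = fp, fn = fn)
}

# Connected-component count via igraph on the pixel-adjacency graph.
oracle_component_count <- function(mask, connectivity = 8L) {
  idx <- which(mask)
  if (!length(idx)) return(0L)
  H <- nrow(mask)
  r <- (idx - 1L) %% H + 1L; cc <- (idx - 1L) %/% H + 1L
  key <- function(rr, ccc) paste(rr, ccc)
  nodes <- key(r, cc)
  offs <- if (connectivity == 8L)
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  edges <- character(0)
  node_set <- new.env(); for (n in nodes) assign(n, TRUE, node_set)
  for (o in offs) {
    nb <- key(r + o[1], cc + o[2])
    ok <- vapply(nb, function(n) exists(n, node_set, inherits = FALSE), TRUE)
    edges <- c(edges, rbind(nodes[ok], nb[ok]))
  }
  g <- igraph::graph_from_data_frame(
    if (length(edges)) data.frame(from = edges[c(TRUE, FALSE)],
                                  to = edges[c(FALSE, TRUE)])
    else data.frame(from = character(0), to = character(0)),
    directed = FALSE, vertices = data.frame(name = nodes))
  igraph::count_components(g)
}
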