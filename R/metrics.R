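# Evaluation metrics for instance segmentation: pixel Dice (DICE1),
# object-level ensemble Dice (DICE2), aggregated Jaccard index (AJI) and
# panoptic quality (PQ = DQ x SQ), plus per-nucleus areas and the
# area-correlation downstream check.
#
# All metrics are computed on the 0-1 scale; reporting tools offer a
# percent view. Instance labels are matched by pixel overlap; relabeling
# instances never changes any metric.

check_same_shape <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) err_shape("pred and truth shapes differ")
}

# Sparse overlap summary of two label maps: per-label areas and the
# intersection size of every overlapping (gt, pred) label pair.
overlap_summary <- function(pred, truth) {
  p <- as.vector(unclass(pred)); g <- as.vector(unclass(truth))
  gt_labels <- setdiff(sort(unique(g)), 0L)
  pr_labels <- setdiff(sort(unique(p)), 0L)
  gt_area <- if (length(gt_labels)) tabulate(match(g, gt_labels), length(gt_labels)) else integer(0)
  pr_area <- if (length(pr_labels)) tabulate(match(p, pr_labels), length(pr_labels)) else integer(0)
  both <- p > 0L & g > 0L
  if (any(both)) {
    key <- paste(g[both], p[both])
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
    pairs <- data.frame(gt = as.integer(parts[, 1]), pred = as.integer(parts[, 2]),
                        intersection = as.integer(tab))
    pairs$gt_area <- gt_area[match(pairs$gt, gt_labels)]
    pairs$pred_area <- pr_area[match(pairs$pred, pr_labels)]
    pairs$union <- pairs$gt_area + pairs$pred_area - pairs$intersection
    pairs$iou <- pairs$intersection / pairs$union
    pairs <- pairs[order(pairs$gt, pairs$pred), , drop = FALSE]
  } else {
    pairs <- data.frame(gt = integer(0), pred = integer(0),
                        intersection = integer(0), gt_area = integer(0),
                        pred_area = integer(0), union = integer(0), iou = numeric(0))
  }
  list(gt_labels = gt_labels, pr_labels = pr_labels,
       gt_area = gt_area, pr_area = pr_area, pairs = pairs)
}

#' Pixel-level Dice coefficient (DICE1)
#'
#' `2 |P intersect G| / (|P| + |G|)` over the binarised foregrounds;
#' defined as 1 when both masks are empty.
#'
#' @param pred,truth [instance_mask()]s of the same shape.
#' @return Scalar in \[0, 1\].
#' @export
dice1 <- function(pred, truth) {
  check_same_shape(pred, truth)
  p <- unclass(pred) > 0L; g <- unclass(truth) > 0L
  sp <- sum(p); sg <- sum(g)
  if (sp + sg == 0L) return(1)
  2 * sum(p & g) / (sp + sg)
}

#' Object-level ensemble Dice (DICE2)
#'
#' Each ground-truth object is matched to the prediction of maximal
#' overlap and vice versa; per-pair `2 |p intersect g|` and `|p| + |g|`
#' accumulate over both directions and the ratio of sums is returned.
#' Objects with no overlap contribute their own size to the denominator.
#' Empty vs empty is 1.
#'
#' @param pred,truth [instance_mask()]s of the same shape.
#' @return Scalar in \[0, 1\].
#' @export
dice2 <- function(pred, truth) {
  check_same_shape(pred, truth)
  ov <- overlap_summary(pred, truth)
  if (!length(ov$gt_labels) && !length(ov$pr_labels)) return(1)
  num <- 0; den <- 0
  for (i in seq_along(ov$gt_labels)) {
    sub <- ov$pairs[ov$pairs$gt == ov$gt_labels[i], , drop = FALSE]
    if (nrow(sub)) {
      j <- which.max(sub$intersection)
      num <- num + 2 * sub$intersection[j]
      den <- den + ov$gt_area[i] + sub$pred_area[j]
    } else den <- den + ov$gt_area[i]
  }
  for (i in seq_along(ov$pr_labels)) {
    sub <- ov$pairs[ov$pairs$pred == ov$pr_labels[i], , drop = FALSE]
    if (nrow(sub)) {
      j <- which.max(sub$intersection)
      num <- num + 2 * sub$intersection[j]
      den <- den + ov$pr_area[i] + sub$gt_area[j]
    } else den <- den + ov$pr_area[i]
  }
  num / den
}

#' Aggregated Jaccard Index (AJI)
#'
#' For each ground-truth object the not-yet-used prediction with the
#' highest intersection-over-union is consumed (ties broken by the
#' smallest prediction label); aggregated intersection and union
#' accumulate over these matches, every left-over prediction's size is
#' added to the union, and the ratio is returned. Empty vs empty is 1.
#'
#' @param pred,truth [instance_mask()]s of the same shape.
#' @return Scalar in \[0, 1\].
#' @export
aji <- function(pred, truth) {
  check_same_shape(pred, truth)
  ov <- overlap_summary(pred, truth)
  if (!length(ov$gt_labels) && !length(ov$pr_labels)) return(1)
  used <- logical(length(ov$pr_labels))
  C <- 0; U <- 0
  for (i in seq_along(ov$gt_labels)) {
    sub <- ov$pairs[ov$pairs$gt == ov$gt_labels[i], , drop = FALSE]
    sub <- sub[!used[match(sub$pred, ov$pr_labels)], , drop = FALSE]
    if (nrow(sub)) {
      best <- which(sub$iou == max(sub$iou))
      j <- best[which.min(sub$pred[best])]
      C <- C + sub$intersection[j]
      U <- U + sub$union[j]
      used[match(sub$pred[j], ov$pr_labels)] <- TRUE
    } else {
      U <- U + ov$gt_area[i]
    }
  }
  U <- U + sum(ov$pr_area[!used])
  if (U == 0) return(1)
  C / U
}

#' Panoptic quality with its detection and segmentation factors
#'
#' Pairs with IoU strictly above 0.5 are true positives (such a matching
#' is necessarily one-to-one); `DQ = TP / (TP + FP/2 + FN/2)`, `SQ` is the
#' mean IoU over true positives (0 if none), and `PQ = DQ * SQ`. Both
#' masks empty yields DQ = SQ = PQ = 1.
#'
#' @param pred,truth [instance_mask()]s of the same shape.
#' @return List with `dq`, `sq`, `pq`, `tp`, `fp`, `fn` and `match_table`
#'   (matched pairs plus `unmatched_gt` / `unmatched_pred` labels).
#' @export
panoptic_quality <- function(pred, truth) {
  check_same_shape(pred, truth)
  ov <- overlap_summary(pred, truth)
  matched <- ov$pairs[ov$pairs$iou > 0.5, , drop = FALSE]
  tp <- nrow(matched)
  fp <- length(ov$pr_labels) - tp
  fn <- length(ov$gt_labels) - tp
  if (length(ov$gt_labels) == 0L && length(ov$pr_labels) == 0L) {
    dq <- sq <- pq <- 1
  } else {
    dq <- tp / (tp + fp / 2 + fn / 2)
    sq <- if (tp > 0) mean(matched$iou) else 0
    pq <- dq * sq
  }
  list(dq = dq, sq = sq, pq = pq, tp = tp, fp = fp, fn = fn,
       match_table = list(
         pairs = matched[, c("gt", "pred", "intersection", "union", "iou")],
         unmatched_gt = setdiff(ov$gt_labels, matched$gt),
         unmatched_pred = setdiff(ov$pr_labels, matched$pred)))
}

#' Full metric report for one prediction/ground-truth pair
#'
#' @param pred,truth [instance_mask()]s of the same shape.
#' @return A `metric_report`: list with `dice1`, `dice2`, `aji`, `dq`,
#'   `sq`, `pq`, `tp`, `fp`, `fn`.
#' @export
evaluate_masks <- function(pred, truth) {
  pq <- panoptic_quality(pred, truth)
  structure(list(dice1 = dice1(pred, truth), dice2 = dice2(pred, truth),
                 aji = aji(pred, truth), dq = pq$dq, sq = pq$sq, pq = pq$pq,
                 tp = pq$tp, fp = pq$fp, fn = pq$fn),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("DICE1 %.4f  DICE2 %.4f  AJI %.4f  DQ %.4f  SQ %.4f  PQ %.4f (TP %d FP %d FN %d)\n",
              x$dice1, x$dice2, x$aji, x$dq, x$sq, x$pq, x$tp, x$fp, x$fn))
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  data.frame(dice1 = x$dice1, dice2 = x$dice2, aji = x$aji,
             dq = x$dq, sq = x$sq, pq = x$pq, tp = x$tp, fp = x$fp, fn = x$fn)
}

#' Per-nucleus areas
#'
#' @param mask An [instance_mask()].
#' @return data.frame with columns `label`, `area` (pixels), sorted by
#'   label.
#' @export
nucleus_areas <- function(mask) {
  labs <- setdiff(sort(unique(as.vector(mask))), 0L)
  if (!length(labs)) return(data.frame(label = integer(0), area = integer(0)))
  data.frame(label = labs,
             area = tabulate(match(as.vector(mask), labs), length(labs)))
}

#' Correlation of matched nucleus areas
#'
#' Ground-truth and predicted objects are matched one-to-one greedily by
#' descending IoU; the Pearson correlation of the matched areas is the
#' downstream consistency check. Unmatched objects are reported but
#' excluded from the correlation.
#'
#' @param pred,truth [instance_mask()]s of the same shape.
#' @return List with `pearson_r`, `pairs` (data.frame gt / pred /
#'   gt_area / pred_area / iou), `unmatched_gt`, `unmatched_pred`.
#' @export
area_correlation <- function(pred, truth) {
  check_same_shape(pred, truth)
  ov <- overlap_summary(pred, truth)
  pr <- ov$pairs[order(-ov$pairs$iou, ov$pairs$gt, ov$pairs$pred), , drop = FALSE]
  used_g <- used_p <- character(0)
  keep <- logical(nrow(pr))
  for (i in seq_len(nrow(pr))) {
    gk <- as.character(pr$gt[i]); pk <- as.character(pr$pred[i])
    if (!(gk %in% used_g) && !(pk %in% used_p)) {
      keep[i] <- TRUE; used_g <- c(used_g, gk); used_p <- c(used_p, pk)
    }
  }
  m <- pr[keep, , drop = FALSE]
  if (nrow(m) < 3L)
    err_insufficient(sprintf("only %d matched object pairs; need at least 3", nrow(m)))
  r <- if (stats::sd(m$gt_area) == 0 || stats::sd(m$pred_area) == 0) 1
  else stats::cor(m$gt_area, m$pred_area)
  list(pearson_r = r,
       pairs = m[, c("gt", "pred", "gt_area", "pred_area", "iou")],
       unmatched_gt = setdiff(ov$gt_labels, m$gt),
       unmatched_pred = setdiff(ov$pr_labels, m$pred))
}
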