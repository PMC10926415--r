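#' Match predicted annotations to ground truth
#'
#' Greedy one-to-one matching in descending prediction score: each
#' prediction claims the unmatched ground-truth annotation of highest
#' bounding-box IoU, provided the IoU reaches `iou_threshold`. Remaining
#' predictions are false positives; remaining ground truths are false
#' negatives. For matched polyline-polyline pairs the polyline Hausdorff
#' distance and the signed length difference (prediction minus truth) are
#' reported as well.
#'
#' @param pred,gt Lists of [annotation()] objects from the same image.
#' @param iou_threshold Minimum IoU for a match (default 0.5).
#' @param bbox_pad Symmetric bounding-box padding in pixels applied to
#'   both sides before computing IoU (default 0). Useful when truth
#'   polylines are centrelines of blurs with physical width: a perfectly
#'   straight centreline has a zero-area box.
#' @return List with `matches` (tibble: `pred_index`, `gt_index`, `iou`,
#'   `pred_score`, `hausdorff`, `length_diff`), `fp` (unmatched prediction
#'   indices) and `fn` (unmatched ground-truth indices).
#' @export
match_annotations <- function(pred, gt, iou_threshold = 0.5, bbox_pad = 0) {
  pad <- function(b) b + c(-1, -1, 1, 1) * bbox_pad
  pb <- lapply(pred, function(a) pad(bbox_of(a)))
  gb <- lapply(gt, function(a) pad(bbox_of(a)))
  scores <- vapply(pred, function(a) {
    if (is.na(a$score)) 1 else a$score
  }, numeric(1))
  ord <- order(-scores, seq_along(pred))
  gt_taken <- rep(FALSE, length(gt))
  rows <- list()
  for (pi in ord) {
    if (length(gt) == 0) break
    ious <- vapply(seq_along(gt), function(gi) {
      if (gt_taken[gi]) -1 else bbox_iou(pb[[pi]], gb[[gi]])
    }, numeric(1))
    gi <- which.max(ious)
    if (ious[gi] >= iou_threshold) {
      gt_taken[gi] <- TRUE
      met <- annotation_metrics(pred[[pi]], gt[[gi]])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        pred_index = pi, gt_index = gi, iou = ious[gi],
        pred_score = scores[pi], hausdorff = met$hausdorff,
        length_diff = met$length_diff)
    }
  }
  matches <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(pred_index = integer(0), gt_index = integer(0),
                   iou = numeric(0), pred_score = numeric(0),
                   hausdorff = numeric(0), length_diff = numeric(0))
  list(matches = matches,
       fp = setdiff(seq_along(pred), matches$pred_index),
       fn = which(!gt_taken))
}

#' Annotation-quality metrics for a matched pair
#'
#' @param pred,gt Matched [annotation()] objects.
#' @return List with `iou` (bounding boxes), and — for polyline-polyline
#'   pairs only — `hausdorff` (px) and `length_diff` (px, prediction minus
#'   truth); `NA` otherwise.
#' @export
annotation_metrics <- function(pred, gt) {
  res <- list(iou = bbox_iou(bbox_of(pred), bbox_of(gt)),
              hausdorff = NA_real_, length_diff = NA_real_)
  if (pred$kind == "polyline" && gt$kind == "polyline") {
    res$hausdorff <- hausdorff_distance(pred$shape, gt$shape)
    res$length_diff <- polyline_length(pred$shape) -
      polyline_length(gt$shape)
  }
  res
}

#' Precision-recall curve over prediction score thresholds
#'
#' For each threshold in the descending set of unique prediction scores,
#' predictions scoring at least the threshold are matched per image and
#' the pooled true/false positive and false negative counts give one
#' precision-recall point. Precision is 1 by convention when no
#' predictions are kept; recall is 0 when there is no ground truth.
#'
#' @param pred,gt Lists of per-image annotation lists (`pred[[i]]` and
#'   `gt[[i]]` belong to the same image). All predictions must carry
#'   scores.
#' @inheritParams match_annotations
#' @return A tibble of class `"pr_curve"` with columns `threshold`,
#'   `precision`, `recall`, `tp`, `fp`, `fn`; one row per threshold,
#'   descending.
#' @export
precision_recall_curve <- function(pred, gt, iou_threshold = 0.5,
                                   bbox_pad = 0) {
  stopifnot(length(pred) == length(gt))
  all_scores <- unlist(lapply(pred, function(pl) {
    vapply(pl, `[[`, numeric(1), "score")
  }))
  if (length(all_scores) > 0 && anyNA(all_scores)) {
    stop("precision_recall_curve: all predictions must carry scores",
         call. = FALSE)
  }
  n_gt <- sum(lengths(gt))
  if (length(all_scores) == 0) {
    out <- tibble::tibble(threshold = NA_real_, precision = 1, recall = 0,
                          tp = 0L, fp = 0L, fn = as.integer(n_gt))
    class(out) <- c("pr_curve", class(out))
    return(out)
  }
  thresholds <- sort(unique(all_scores), decreasing = TRUE)
  out <- purrr::map_dfr(thresholds, function(th) {
    tp <- 0L; fp <- 0L; fn <- 0L
    for (i in seq_along(pred)) {
      kept <- purrr::keep(pred[[i]], function(a) a$score >= th)
      m <- match_annotations(kept, gt[[i]], iou_threshold, bbox_pad)
      tp <- tp + nrow(m$matches)
      fp <- fp + length(m$fp)
      fn <- fn + length(m$fn)
    }
    tibble::tibble(
      threshold = th,
      precision = if (tp + fp == 0) 1 else tp / (tp + fp),
      recall = if (tp + fn == 0) 0 else tp / (tp + fn),
      tp = tp, fp = fp, fn = fn)
  })
  class(out) <- c("pr_curve", class(out))
  out
}

#' Score recovered trajectories against synthetic ground truth
#'
#' Assigns each polyline detection of each trajectory to the nearest truth
#' polyline of the same maximum image (by matching distance, within
#' `match_threshold`), then summarizes identity bookkeeping: a truth track
#' is recovered unfragmented when exactly one trajectory carries its
#' identity; a trajectory with detections from more than one identity is
#' an identity swap.
#'
#' @param trajs A `trajectory_set` or list of [trajectory()] objects.
#' @param pair_truth Tibble with columns `pair_index`, `identity` and
#'   `poly` (list column of truth [polyline()]s per maximum image), as
#'   produced by [sequence_pair_truth()].
#' @param match_threshold Maximum matching distance for a detection-truth
#'   assignment (default 40 px).
#' @return List with `per_trajectory` (tibble: trajectory, identity,
#'   n_detections, n_identities) and `summary` (tibble: n_true,
#'   n_trajectories, n_recovered, n_fragmented, identity_swaps,
#'   recovery_rate).
#' @export
evaluate_tracking <- function(trajs, pair_truth, match_threshold = 40) {
  skeleton <- tibble::tibble(trajectory = integer(0),
                             identity = character(0),
                             n_detections = integer(0),
                             n_identities = integer(0))
  per_traj <- purrr::map_dfr(seq_along(trajs), function(ti) {
    tr <- trajs[[ti]]
    ids <- character(0)
    for (d in tr$detections) {
      if (d$annotation$kind != "polyline") next
      cand <- pair_truth[pair_truth$pair_index == d$pair_index, ]
      if (nrow(cand) == 0) next
      dm <- vapply(cand$poly, function(tp) {
        matching_distance(d$annotation$shape, tp)
      }, numeric(1))
      if (min(dm) <= match_threshold) {
        ids <- c(ids, as.character(cand$identity[which.min(dm)]))
      }
    }
    tibble::tibble(
      trajectory = ti,
      identity = if (length(ids)) names(sort(table(ids),
                                             decreasing = TRUE))[1]
                 else NA_character_,
      n_detections = tr$n_detections,
      n_identities = length(unique(ids)))
  })
  if (nrow(per_traj) == 0) per_traj <- skeleton
  true_ids <- unique(as.character(pair_truth$identity))
  claimed <- table(per_traj$identity[!is.na(per_traj$identity)])
  n_recovered <- sum(claimed == 1 & names(claimed) %in% true_ids)
  n_fragmented <- sum(claimed > 1)
  swaps <- sum(per_traj$n_identities > 1)
  summary <- tibble::tibble(
    n_true = length(true_ids),
    n_trajectories = length(trajs),
    n_recovered = n_recovered,
    n_fragmented = n_fragmented,
    identity_swaps = swaps,
    recovery_rate = if (length(true_ids)) n_recovered / length(true_ids)
                    else NA_real_)
  list(per_trajectory = per_traj, summary = summary)
}
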