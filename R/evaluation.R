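# Evaluation protocol: per-subject Dice (both / left / right), voxelwise
# precision and recall, and cohort aggregation into mean +/- sd tables.
#
# Empty-mask conventions (these are what make a hallucinated mask on a
# resected side score 0 and pull the cohort mean down):
#   * Dice: both masks empty -> 1; ground truth empty but prediction not
#     (or vice versa) -> 0.
#   * precision / recall: a 0/0 denominator yields 1 only when both masks
#     are empty, otherwise 0.

#' Overlap Dice between two binary masks
#'
#' `2|P & G| / (|P| + |G|)` (identical to the squared-sum form on binary
#' input). Both masks empty returns 1 by convention.
#'
#' @param p,g [label_volume()]s or binary arrays on the same grid.
#' @export
dice_binary <- function(p, g) {
  pd <- if (inherits(p, "label_volume")) p$data else p
  gd <- if (inherits(g, "label_volume")) g$data else g
  check_same_shape(pd, gd)
  sp <- sum(pd)
  sg <- sum(gd)
  if (sp == 0 && sg == 0) return(1)
  2 * sum(pd * gd) / (sp + sg)
}

#' Voxelwise precision and recall
#'
#' Precision = TP / (TP + FP), recall = TP / (TP + FN), where positives
#' are structure voxels.
#'
#' @param p,g prediction and ground truth masks on the same grid.
#' @return Named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(p, g) {
  pd <- if (inherits(p, "label_volume")) p$data else p
  gd <- if (inherits(g, "label_volume")) g$data else g
  check_same_shape(pd, gd)
  tp <- sum(pd * gd)
  fp <- sum(pd) - tp
  fn <- sum(gd) - tp
  if (sum(pd) == 0 && sum(gd) == 0) return(c(precision = 1, recall = 1))
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  c(precision = prec, recall = rec)
}

#' Split a canonical mask at the mid-sagittal grid plane
#'
#' The grid is partitioned at the sagittal mid-plane; for an odd extent
#' the mid-plane voxels are assigned to the left half. "Left" is the
#' lower-index half of the first (left-to-right) canonical axis.
#'
#' @param m a [label_volume()] on the canonical grid.
#' @return List with [label_volume()]s `left` and `right` (full-size masks
#'   zeroed outside their half).
#' @export
split_left_right <- function(m) {
  stopifnot(inherits(m, "label_volume"))
  nx <- dim(m$data)[1]
  lx <- as.integer(ceiling(nx / 2))
  left <- m$data
  right <- m$data
  left[(lx + 1L):nx, , ] <- 0L
  right[1:lx, , ] <- 0L
  list(left = label_volume(left, m$affine),
       right = label_volume(right, m$affine))
}

eval_record <- function(id, pred, gt, tag) {
  if (!inherits(pred, "label_volume")) pred <- label_volume(pred)
  if (!inherits(gt, "label_volume")) gt <- label_volume(gt)
  ps <- split_left_right(pred)
  gs <- split_left_right(gt)
  pr <- precision_recall(pred, gt)
  data.frame(id = id, cohort = tag,
             dice_both = dice_binary(pred, gt),
             dice_left = dice_binary(ps$left, gs$left),
             dice_right = dice_binary(ps$right, gs$right),
             precision = unname(pr["precision"]),
             recall = unname(pr["recall"]),
             stringsAsFactors = FALSE)
}

#' Evaluate a cohort of predictions against ground truth
#'
#' Computes per-subject Dice over both structures and over the left and
#' right grid halves separately, plus voxelwise precision and recall, and
#' aggregates mean and population standard deviation per cohort tag.
#'
#' @param predictions named list (by subject id) of predicted
#'   [label_volume()]s on the canonical grid.
#' @param ground_truths named list of matching ground-truth masks.
#' @param tags named character vector of cohort tags (e.g. control /
#'   patient); defaults to a single group.
#' @return List with `records` (per-subject data frame) and `summary`
#'   (mean/sd per tag and metric).
#' @export
evaluate_cohort <- function(predictions, ground_truths, tags = NULL) {
  ids <- names(predictions)
  if (is.null(ids) || !setequal(ids, names(ground_truths)))
    e2d_stop("prediction and ground-truth subject ids do not match",
             "e2d_pairing_error")
  if (is.null(tags)) tags <- stats::setNames(rep("all", length(ids)), ids)
  records <- do.call(rbind, lapply(ids, function(id)
    eval_record(id, predictions[[id]], ground_truths[[id]], tags[[id]])))
  metrics <- c("dice_both", "dice_left", "dice_right", "precision", "recall")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  summary <- do.call(rbind, lapply(split(records, records$cohort), function(d) {
    data.frame(cohort = d$cohort[1], metric = metrics,
               mean = vapply(metrics, function(m) mean(d[[m]]), numeric(1)),
               sd = vapply(metrics, function(m) pop_sd(d[[m]]), numeric(1)),
               n = nrow(d), row.names = NULL, stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(records = records, summary = summary)
}
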