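#' @title Segmentation evaluation suite
#' @description Per-class one-vs-rest voxel metrics (Dice, IoU, accuracy,
#'   precision, sensitivity, F1), their macro averages
#'   (`mEM = (1/N) sum EM_i` over the `N` included classes), and the
#'   present/absent identification accounting for classes that are empty
#'   in the ground truth (tooth loss, restorations, implants) or missing
#'   from the prediction.
#' @name metrics
NULL

check_same_grid <- function(a, b) {
  da <- dim(grid_of(a)); db <- dim(grid_of(b))
  if (!identical(da, db)) {
    stop("label grids differ: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
  }
}

#' One-vs-rest confusion counts for a class
#'
#' @param pred,gt [label_volume()]s on the same grid.
#' @param class_k Class index (0 = background allowed).
#' @return Named numeric `c(TP, FP, FN, TN)`; the four sum to the voxel
#'   count.
#' @export
confusion_counts <- function(pred, gt, class_k) {
  check_same_grid(pred, gt)
  p <- pred$labels == class_k
  g <- gt$labels == class_k
  tp <- sum(p & g)
  fp <- sum(p & !g)
  fn <- sum(!p & g)
  c(TP = tp, FP = fp, FN = fn, TN = length(p) - tp - fp - fn)
}

#' Per-class metrics from confusion counts
#'
#' `dice = 2TP/(2TP+FP+FN)`, `iou = TP/(TP+FP+FN)`,
#' `accuracy = (TP+TN)/total`, `precision = TP/(TP+FP)`,
#' `sensitivity = TP/(TP+FN)`; for binary voxel counts F1 equals Dice
#' (the harmonic-mean identity) and is reported as such. Degenerate
#' denominators (class empty in both prediction and truth) yield `NaN`;
#' such classes carry no voxel evidence and are excluded from macro
#' averages by [evaluate_case()].
#'
#' @param TP,FP,FN,TN Nonnegative counts.
#' @return Named numeric with `dice`, `iou`, `accuracy`, `precision`,
#'   `sensitivity`, `f1`.
#' @export
class_metrics <- function(TP, FP, FN, TN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0, TN >= 0)
  total <- TP + FP + FN + TN
  dice <- if (2 * TP + FP + FN == 0) NaN else 2 * TP / (2 * TP + FP + FN)
  iou <- if (TP + FP + FN == 0) NaN else TP / (TP + FP + FN)
  prec <- if (TP + FP == 0) NaN else TP / (TP + FP)
  sens <- if (TP + FN == 0) NaN else TP / (TP + FN)
  c(dice = dice, iou = iou, accuracy = (TP + TN) / total,
    precision = prec, sensitivity = sens, f1 = dice)
}

#' Macro average over an included class set
#'
#' The unweighted mean of per-class metric values over exactly the
#' included classes (`mEM` with `N = length(included)`).
#'
#' @param values Named numeric vector of per-class values (names are
#'   class indices) or unnamed vector.
#' @param included Class names/indices to include; default all.
#' @return List with `mean` and `n`.
#' @export
macro_average <- function(values, included = NULL) {
  if (!is.null(included)) {
    values <- if (!is.null(names(values))) values[as.character(included)]
              else values[included]
  }
  if (length(values) == 0L || all(is.na(values))) {
    stop("macro_average over an empty class set")
  }
  list(mean = mean(values, na.rm = FALSE), n = length(values))
}

joint_confusion <- function(pred, gt, K) {
  # (K+1) x (K+1) matrix: rows = predicted class 0..K, cols = truth
  joint <- as.integer(gt) * (K + 1L) + as.integer(pred) + 1L
  matrix(tabulate(joint, nbins = (K + 1L)^2), K + 1L, K + 1L)
}

#' Present/absent identification accounting
#'
#' A class is *ground-truth empty* when it has zero voxels in the truth
#' (a label marked empty due to tooth loss, restorations, or implants);
#' it is *predicted present* when its predicted voxel count is at least
#' `min_voxels`. The tally reports `correct_identify` (gt-empty predicted
#' empty), `false_identify` (gt-empty predicted present) and
#' `missing_segment` (gt-present predicted empty), with
#' `correct_identify + false_identify` equal to the number of gt-empty
#' classes.
#'
#' @param pred,gt [label_volume()]s on the same grid.
#' @param scheme Label scheme (default [default_scheme()]).
#' @param min_voxels Presence threshold for predictions (>= 1).
#' @return An object of class `identification_tally`: counts plus a
#'   per-class flag table.
#' @export
tally_identification <- function(pred, gt, scheme = default_scheme(),
                                 min_voxels = 1L) {
  check_same_grid(pred, gt)
  stopifnot(min_voxels >= 1L)
  K <- max(scheme$index)
  gt_n <- tabulate(as.integer(gt$labels), nbins = K)
  pr_n <- tabulate(as.integer(pred$labels), nbins = K)
  gt_present <- gt_n > 0L
  pr_present <- pr_n >= min_voxels
  flags <- data.frame(
    class = scheme$index,
    gt_voxels = gt_n,
    pred_voxels = pr_n,
    gt_present = gt_present,
    pred_present = pr_present,
    correct_identify = !gt_present & !pr_present,
    false_identify = !gt_present & pr_present,
    missing_segment = gt_present & !pr_present
  )
  structure(list(
    correct_identify = sum(flags$correct_identify),
    false_identify = sum(flags$false_identify),
    missing_segment = sum(flags$missing_segment),
    n_gt_empty = sum(!gt_present),
    per_class = flags
  ), class = "identification_tally")
}

#' @export
print.identification_tally <- function(x, ...) {
  cat(sprintf(
    "<identification tally> correct %d / false %d (of %d gt-empty); missing %d\n",
    x$correct_identify, x$false_identify, x$n_gt_empty, x$missing_segment))
  invisible(x)
}

#' Metrics policy
#'
#' @param include_background Include class 0 in macro averages?
#' @param score_false_identify Score gt-empty classes that were predicted
#'   non-empty as Dice 0 inside the macro average (default `FALSE`: they
#'   are routed to the identification tally only).
#' @param min_voxels Presence threshold for the tally.
#' @return A list of class `metrics_policy`.
#' @export
metrics_policy <- function(include_background = FALSE,
                           score_false_identify = FALSE,
                           min_voxels = 1L) {
  structure(list(include_background = include_background,
                 score_false_identify = score_false_identify,
                 min_voxels = as.integer(min_voxels)),
            class = "metrics_policy")
}

#' Evaluate one predicted segmentation against its ground truth
#'
#' Computes per-class one-vs-rest metrics for every class present in the
#' ground truth (plus, policy-controlled, background and falsely
#' predicted gt-empty classes), their macro averages, and the
#' identification tally for empty/unpredicted labels.
#'
#' @param pred,gt [label_volume()]s on the same grid.
#' @param scheme Label scheme (default [default_scheme()]).
#' @param policy A [metrics_policy()].
#' @return List with `report` (class `metrics_report`: `per_class` data
#'   frame, `macro` named vector `mDice`, `mIoU`, `mAccuracy`,
#'   `mPrecision`, `mSensitivity`, `mF1`, and `n_classes_averaged`) and
#'   `tally` (an `identification_tally`).
#' @export
evaluate_case <- function(pred, gt, scheme = default_scheme(),
                          policy = metrics_policy()) {
  check_same_grid(pred, gt)
  K <- max(scheme$index)
  M <- joint_confusion(pred$labels, gt$labels, K)
  total <- sum(M)
  gt_n <- colSums(M)   # truth voxel count per class 0..K
  pr_n <- rowSums(M)
  tally <- tally_identification(pred, gt, scheme, policy$min_voxels)

  classes <- 0:K
  eligible <- gt_n > 0
  if (policy$score_false_identify) {
    eligible <- eligible | (pr_n >= policy$min_voxels)
  }
  if (!policy$include_background) eligible[1] <- FALSE
  sel <- classes[eligible]
  rows <- lapply(sel, function(k) {
    tp <- M[k + 1, k + 1]
    fp <- pr_n[k + 1] - tp
    fn <- gt_n[k + 1] - tp
    m <- class_metrics(tp, fp, fn, total - tp - fp - fn)
    data.frame(class = k, t(m), gt_voxels = gt_n[k + 1],
               pred_voxels = pr_n[k + 1])
  })
  per_class <- do.call(rbind, rows)
  metric_cols <- c("dice", "iou", "accuracy", "precision", "sensitivity", "f1")
  macro <- vapply(metric_cols, function(mc) {
    mean(per_class[[mc]])
  }, numeric(1))
  names(macro) <- c("mDice", "mIoU", "mAccuracy", "mPrecision",
                    "mSensitivity", "mF1")
  report <- structure(list(per_class = per_class, macro = macro,
                           n_classes_averaged = nrow(per_class)),
                      class = "metrics_report")
  list(report = report, tally = tally)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics report> N=%d classes: %s\n", x$n_classes_averaged,
              paste(sprintf("%s=%.4f", names(x$macro), x$macro),
                    collapse = " ")))
  invisible(x)
}

#' Aggregate per-case reports by unweighted mean
#'
#' Macro-over-cases: the mean of each case's macro metrics, with the
#' per-case values returned so any other aggregation can be recomputed.
#'
#' @param results List of results from [evaluate_case()].
#' @return List with `summary` (named means) and `per_case` data frame.
#' @export
aggregate_reports <- function(results) {
  stopifnot(length(results) >= 1L)
  per_case <- do.call(rbind, lapply(seq_along(results), function(i) {
    data.frame(case = i, t(results[[i]]$report$macro),
               n_classes = results[[i]]$report$n_classes_averaged)
  }))
  metric_cols <- setdiff(names(per_case), c("case", "n_classes"))
  summary <- colMeans(per_case[metric_cols])
  list(summary = summary, per_case = per_case)
}
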