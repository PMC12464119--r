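test_that("confusion counts match brute-force voxel enumeration", {
  pair <- random_label_pair(c(5, 5, 5), K = 4, seed = 31)
  for (k in 0:4) {
    cc <- confusion_counts(pair$pred, pair$gt, k)
    oc <- oracle_class_metrics(as.integer(pair$pred$labels),
                               as.integer(pair$gt$labels), k)
    expect_equal(unname(cc), unname(oc[c("TP", "FP", "FN", "TN")]))
    expect_equal(sum(cc), 125)
  }
  expect_error(confusion_counts(pair$pred,
                                label_volume(array(0L, c(4, 4, 4))), 1),
               "grids differ")
  # perfect prediction has no off-diagonal mass
  cc <- confusion_counts(pair$gt, pair$gt, 2)
  expect_equal(unname(cc[c("FP", "FN")]), c(0, 0))
})

test_that("class metrics implement the stated formulas", {
  m <- class_metrics(3, 3, 1, 10)
  expect_equal(unname(m["dice"]), 0.6)
  expect_equal(unname(m["iou"]), 3 / 7)
  expect_equal(unname(m["accuracy"]), 13 / 17)
  expect_equal(unname(m["precision"]), 0.5)
  expect_equal(unname(m["sensitivity"]), 0.75)
  perfect <- class_metrics(10, 0, 0, 5)
  expect_true(all(perfect == 1))
  none <- class_metrics(0, 2, 3, 5)
  expect_equal(unname(none["dice"]), 0)
  expect_equal(unname(none["iou"]), 0)
})

test_that("f1 equals dice and iou <= dice on random counts", {
  set.seed(32)
  for (i in 1:50) {
    cnt <- sample(0:30, 4, TRUE)
    m <- class_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    if (!is.nan(m["dice"])) {
      expect_equal(unname(m["f1"]), unname(m["dice"]))
      expect_lte(m["iou"], m["dice"] + 1e-12)
      if (m["dice"] > 0 && m["dice"] < 1) expect_lt(m["iou"], m["dice"])
    }
  }
})

test_that("macro average is the unweighted mean over included classes", {
  expect_equal(macro_average(c(0.8, 0.9, 1.0))$mean, 0.9)
  expect_equal(macro_average(c(a = 0.4, b = 0.6), included = "b")$mean, 0.6)
  expect_equal(macro_average(0.7)$n, 1L)
  expect_equal(macro_average(rep(0.55, 9))$mean, 0.55)
  expect_error(macro_average(numeric(0)), "empty")
})

test_that("identification tally follows the presence definitions", {
  dims <- c(8, 8, 4)
  gt <- array(0L, dims); pred <- array(0L, dims)
  # gt present {1, 2, 33, 34}, gt empty includes 3; pred present {1, 3, 33, 34}
  gt[1:20] <- 1L; gt[21:40] <- 2L; gt[41:60] <- 33L; gt[61:80] <- 34L
  pred[1:20] <- 1L; pred[21:40] <- 3L; pred[41:60] <- 33L; pred[61:80] <- 34L
  tal <- tally_identification(label_volume(pred), label_volume(gt))
  expect_equal(tal$false_identify, 1)        # class 3
  expect_equal(tal$missing_segment, 1)       # class 2
  expect_equal(tal$correct_identify, tal$n_gt_empty - 1)
  expect_equal(tal$correct_identify + tal$false_identify, tal$n_gt_empty)
  # min_voxels threshold reclassifies small blobs as absent
  pred2 <- pred; pred2[21:40] <- 0L; pred2[21] <- 3L
  t2 <- tally_identification(label_volume(pred2), label_volume(gt),
                             min_voxels = 5L)
  expect_equal(t2$false_identify, 0)
})

test_that("evaluate_case separates scored classes from the tally", {
  ph <- small_phantom()
  res <- evaluate_case(ph$labels, ph$labels)
  expect_equal(unname(res$report$macro["mDice"]), 1)
  expect_equal(unname(res$report$macro["mIoU"]), 1)
  expect_equal(res$tally$false_identify, 0)
  expect_equal(res$tally$missing_segment, 0)
  expect_equal(res$tally$correct_identify, res$tally$n_gt_empty)
  # scored classes are exactly the gt-present foreground classes
  expect_setequal(res$report$per_class$class,
                  sort(setdiff(unique(as.integer(ph$labels$labels)), 0L)))

  pert <- perturb_annotation(ph$labels, 0.25, seed = 3)
  r2 <- evaluate_case(pert, ph$labels)
  expect_true(r2$report$macro["mDice"] > 0 && r2$report$macro["mDice"] < 1)
  r2b <- evaluate_case(pert, ph$labels)
  expect_equal(r2$report$macro, r2b$report$macro)
})

test_that("background inclusion inflates accuracy when background dominates", {
  # two small foreground classes that confuse each other against a vast,
  # perfectly-predicted background: the background's one-vs-rest accuracy
  # is 1 and pulls the macro up when included
  dims <- c(10, 10, 10)
  gt <- array(0L, dims); gt[1:30] <- 1L; gt[31:60] <- 2L
  pred <- gt; pred[1:10] <- 2L; pred[31:40] <- 1L
  lvp <- label_volume(pred); lvg <- label_volume(gt)
  no_bg <- evaluate_case(lvp, lvg, policy = metrics_policy())$report
  with_bg <- evaluate_case(lvp, lvg,
                           policy = metrics_policy(include_background = TRUE))$report
  expect_gt(with_bg$macro["mAccuracy"], no_bg$macro["mAccuracy"])
  expect_equal(with_bg$n_classes_averaged, no_bg$n_classes_averaged + 1L)
})

test_that("metrics are invariant under a common spatial permutation", {
  pair <- random_label_pair(c(6, 6, 6), K = 5, seed = 33)
  perm <- sample(216)
  pp <- label_volume(array(pair$pred$labels[perm], c(6, 6, 6)))
  gp <- label_volume(array(pair$gt$labels[perm], c(6, 6, 6)))
  a <- evaluate_case(pair$pred, pair$gt)$report
  b <- evaluate_case(pp, gp)$report
  expect_equal(a$macro, b$macro)
})

test_that("case aggregation is the unweighted mean of case macros", {
  ph <- small_phantom()
  r1 <- evaluate_case(ph$labels, ph$labels)
  r2 <- evaluate_case(perturb_annotation(ph$labels, 0.3, seed = 1), ph$labels)
  agg <- aggregate_reports(list(r1, r2))
  expect_equal(unname(agg$summary["mDice"]),
               mean(c(r1$report$macro["mDice"], r2$report$macro["mDice"])))
  expect_equal(nrow(agg$per_case), 2L)
})
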