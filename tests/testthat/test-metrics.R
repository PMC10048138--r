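test_that("confusion matrix counts exactly and detects bad input", {
  gt <- matrix(c(0L, 0L, 1L, 1L), 1, 4)
  pred <- matrix(c(0L, 1L, 1L, 1L), 1, 4)
  cm <- confusion_matrix(gt, pred, n = 2)
  expect_equal(unname(cm$P), matrix(c(1, 0, 1, 2), 2, 2))
  expect_equal(sum(cm$P), 4)
  expect_equal(sum(cm$M), sum(cm$H))

  perfect <- confusion_matrix(gt, gt, n = 2)
  expect_equal(sum(perfect$P) - sum(diag(perfect$P)), 0)

  expect_error(confusion_matrix(list(gt), list(matrix(0L, 2, 2)), 2), "image 1")
})

test_that("accuracy and IoU metrics hit hand-computed values", {
  cm <- confusion_matrix(matrix(c(0L, 0L, 1L, 1L), 2, 2),
                         matrix(c(0L, 1L, 1L, 1L), 2, 2), n = 2)
  expect_equal(global_accuracy(cm), 3 / 4)
  expect_equal(mean_accuracy(cm), 0.75)

  # overlapping 100-pixel sets sharing 60 pixels -> IoU 60/140
  gt <- matrix(0L, 20, 20); gt[1:100] <- 1L
  pr <- matrix(0L, 20, 20); pr[41:140] <- 1L
  cm2 <- confusion_matrix(gt, pr, 2)
  expect_equal(class_iou(cm2, 1L), 60 / 140)

  # wIoU weights per-class IoU by true-pixel share: 90%/10% shares with
  # IoUs 1 and 0 give 0.9 where the unweighted mean would be 0.5
  P <- matrix(c(90, 0, 0, 0, 0, 10, 0, 0, 0), 3, 3, byrow = TRUE)
  cm3 <- structure(list(P = P, M = rowSums(P), H = colSums(P)),
                   class = "confusion_matrix")
  expect_equal(class_iou(cm3, 0L), 1)
  expect_equal(class_iou(cm3, 1L), 0)
  expect_equal(weighted_iou(cm3), 0.9)
})

test_that("reference per-class accuracies average to the printed mean accuracy", {
  per_class <- c(0.7441, 0.8255, 0.8511, 0.9724)
  expect_equal(round(mean(per_class), 4), 0.8483)
})

test_that("boundary maps obey the 4-adjacency/border rule", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  expect_equal(nrow(boundary_map(m)), 1)
  full <- matrix(TRUE, 5, 5)
  b <- boundary_map(full)
  expect_equal(nrow(b), 16)  # one-pixel frame
  expect_equal(nrow(boundary_map(matrix(FALSE, 4, 4))), 0)
})

test_that("boundary precision/recall and bfscore behave per definition", {
  m <- matrix(FALSE, 8, 8); m[3:5, 3:5] <- TRUE
  bm <- boundary_map(m)
  expect_equal(unname(bf_precision_recall(bm, bm, 1)), c(1, 1))

  a <- matrix(c(1L, 1L), 1, 2, byrow = TRUE)[1, , drop = FALSE]
  b2 <- matrix(c(1L, 11L), 1, 2)
  expect_equal(unname(bf_precision_recall(a, b2, 2.7)), c(0, 0))

  # shifted square: max nearest-neighbour distance sqrt(2) < 1.5
  s1 <- matrix(FALSE, 10, 10); s1[3:6, 3:6] <- TRUE
  s2 <- matrix(FALSE, 10, 10); s2[4:7, 4:7] <- TRUE
  pr <- bf_precision_recall(boundary_map(s2), boundary_map(s1), 1.5)
  expect_equal(unname(pr), c(1, 1))

  expect_equal(bf_default_tol(256, 256), 0.0075 * sqrt(2) * 256)
  g <- matrix(0L, 8, 8); g[3:5, 3:5] <- 1L
  expect_equal(bfscore(g, g, 1L), 1)
  expect_true(is.na(bfscore(g, g, 3L)))  # class absent from both -> skipped
})

test_that("bfscore is symmetric in gt/pred and monotone in tolerance", {
  set.seed(21)
  for (i in 1:5) {
    gt <- random_labels(12, 12, 2)
    pr <- random_labels(12, 12, 2)
    expect_equal(bfscore(gt, pr, 1L, 2), bfscore(pr, gt, 1L, 2), tolerance = 1e-12)
    f <- vapply(c(1, 2, 4, 8), function(t) bfscore(gt, pr, 1L, t), numeric(1))
    expect_true(all(diff(f) >= -1e-12))
  }
})

test_that("dataset bfscore averages per image, not per pixel", {
  g1 <- matrix(0L, 6, 6); g1[2:4, 2:4] <- 1L
  pairs <- list(list(gt = g1, pred = g1),
                list(gt = g1, pred = matrix(0L, 6, 6)))
  s1 <- image_bfscore(pairs[[1]]$gt, pairs[[1]]$pred, 1)
  s2 <- image_bfscore(pairs[[2]]$gt, pairs[[2]]$pred, 1)
  expect_equal(dataset_bfscore(pairs, 1), mean(c(s1, s2)))
})

test_that("per-image report is consistent with single-image metrics", {
  set.seed(33)
  pairs <- lapply(1:4, function(i) list(gt = random_labels(10, 10),
                                        pred = random_labels(10, 10)))
  rep <- per_image_report(pairs)
  expect_equal(nrow(rep), 4)
  for (i in 1:4) {
    cm <- confusion_matrix(pairs[[i]]$gt, pairs[[i]]$pred, 4)
    expect_equal(rep$gAcc[i], global_accuracy(cm))
    expect_equal(rep$lge_tp[i], sum(pairs[[i]]$gt == 3 & pairs[[i]]$pred == 3))
    expect_equal(rep$lge_pred[i], sum(pairs[[i]]$pred == 3))
    expect_lte(rep$lge_tp[i], rep$lge_pred[i])
  }
  perf <- per_image_report(list(list(gt = pairs[[1]]$gt, pred = pairs[[1]]$gt)))
  expect_equal(perf$gAcc, 1)
  expect_equal(perf$lge_tp, perf$lge_pred)
})

test_that("gAcc is invariant to a joint class permutation", {
  set.seed(8)
  gt <- random_labels(16, 16)
  pr <- random_labels(16, 16)
  perm <- c(2L, 3L, 0L, 1L)
  g2 <- matrix(perm[gt + 1L], 16, 16)
  p2 <- matrix(perm[pr + 1L], 16, 16)
  expect_equal(global_accuracy(confusion_matrix(gt, pr, 4)),
               global_accuracy(confusion_matrix(g2, p2, 4)))
})
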