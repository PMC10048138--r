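# Segmentation evaluation suite: confusion matrix, accuracies, IoU,
# weighted IoU, boundary F1 with a distance tolerance, per-image reports.
# Convention everywhere: class codes are 0-based (0 background, 1 blood,
# 2 muscle, 3 LGE); confusion-matrix rows are the TRUE class, columns the
# predicted class.

#' Pixel confusion matrix over one or many image pairs
#'
#' `P[a+1, b+1]` counts pixels with true label `a` and predicted label `b`,
#' accumulated over all supplied pairs. Row totals `M` are true-class pixel
#' counts, column totals `H` predicted-class counts.
#'
#' @param gt,pred label matrices (codes in `[0, n)`), or lists of matrices /
#'   [labeled_image]s of equal length.
#' @param n number of classes.
#' @return object of class `confusion_matrix` with fields `P`, `M`, `H`.
#' @export
confusion_matrix <- function(gt, pred, n = 4L) {
  gl <- as_label_list(gt)
  pl <- as_label_list(pred)
  if (length(gl) != length(pl)) stop("confusion_matrix: gt and pred lengths differ")
  P <- matrix(0, n, n)
  for (i in seq_along(gl)) {
    g <- gl[[i]]; p <- pl[[i]]
    if (!all(dim(g) == dim(p)))
      stop(sprintf("confusion_matrix: shape mismatch at image %d (%s vs %s)",
                   i, paste(dim(g), collapse = "x"), paste(dim(p), collapse = "x")))
    if (any(g < 0 | g >= n | p < 0 | p >= n))
      stop(sprintf("confusion_matrix: label out of range at image %d", i))
    P <- P + matrix(tabulate(as.integer(g) * n + as.integer(p) + 1L, nbins = n * n),
                    n, n, byrow = TRUE)
  }
  dimnames(P) <- list(true = 0:(n - 1), predicted = 0:(n - 1))
  structure(list(P = P, M = rowSums(P), H = colSums(P)), class = "confusion_matrix")
}

as_label_list <- function(x) {
  if (inherits(x, "labeled_image")) return(list(x$labels))
  if (is.matrix(x)) return(list(x))
  lapply(x, function(e) if (inherits(e, "labeled_image")) e$labels else e)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion matrix (rows = true class, cols = predicted class)\n")
  print(x$P)
  invisible(x)
}

#' Global accuracy: fraction of all correctly classified pixels
#' @param cm a [confusion_matrix].
#' @return rate in `[0, 1]`.
#' @export
global_accuracy <- function(cm) {
  tot <- sum(cm$P)
  if (tot == 0) stop("global_accuracy: empty confusion matrix")
  sum(diag(cm$P)) / tot
}

#' Mean (class-averaged) accuracy
#'
#' Unweighted mean over classes of the per-class recall `P_aa / M_a`.
#' Classes absent from the ground truth are skipped with a warning and the
#' class count reduced accordingly.
#'
#' @param cm a [confusion_matrix].
#' @return rate in `[0, 1]`.
#' @export
mean_accuracy <- function(cm) {
  present <- cm$M > 0
  if (!all(present))
    warning("mean_accuracy: skipping class(es) absent from ground truth: ",
            paste(which(!present) - 1, collapse = ", "))
  mean(diag(cm$P)[present] / cm$M[present])
}

#' Per-class accuracy (recall) vector
#' @param cm a [confusion_matrix].
#' @return numeric vector, `NA` for classes absent from ground truth.
#' @export
class_accuracy <- function(cm) {
  out <- diag(cm$P) / ifelse(cm$M > 0, cm$M, NA)
  stats::setNames(out, rownames(cm$P))
}

#' Intersection over union of one class
#'
#' `IoU_a = P_aa / (M_a + H_a - P_aa)`: correct pixels over the union of
#' ground-truth and predicted pixels of that class. `NA` when the class is
#' absent from both.
#'
#' @param cm a [confusion_matrix].
#' @param class 0-based class code.
#' @return rate in `[0, 1]` or `NA`.
#' @export
class_iou <- function(cm, class) {
  a <- class + 1L
  den <- cm$M[a] + cm$H[a] - cm$P[a, a]
  if (den == 0) return(NA_real_)
  unname(cm$P[a, a] / den)
}

#' Weighted intersection over union
#'
#' Per-class IoU averaged with weights proportional to each class's
#' true-pixel share, damping the influence of small classes.
#'
#' @param cm a [confusion_matrix].
#' @return rate in `[0, 1]`.
#' @export
weighted_iou <- function(cm) {
  tot <- sum(cm$P)
  if (tot == 0) stop("weighted_iou: empty confusion matrix")
  n <- nrow(cm$P)
  acc <- 0
  for (a in seq_len(n)) {
    if (cm$M[a] == 0) next
    acc <- acc + unname(cm$M[a] / tot) * class_iou(cm, a - 1L)
  }
  acc
}

#' Mean IoU over classes present in ground truth or prediction
#' @param cm a [confusion_matrix].
#' @return rate in `[0, 1]`.
#' @export
mean_iou <- function(cm) {
  ious <- vapply(seq_len(nrow(cm$P)) - 1L, function(a) class_iou(cm, a), numeric(1))
  mean(ious, na.rm = TRUE)
}

#' Boundary pixels of a binary mask
#'
#' A mask pixel belongs to the boundary when at least one of its 4-neighbours
#' is outside the mask; the image border counts as outside.
#'
#' @param mask logical matrix.
#' @return `n x 2` integer matrix of (row, col) coordinates, class
#'   `boundary_map`.
#' @export
boundary_map <- function(mask) {
  mask <- mask != 0
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  interior <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  structure(which(mask & !interior, arr.ind = TRUE), class = "boundary_map")
}

# min Euclidean distance from each row of A to the point set B
min_dists <- function(a, b) {
  if (nrow(a) == 0) return(numeric(0))
  if (nrow(b) == 0) return(rep(Inf, nrow(a)))
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

#' Boundary precision and recall under a distance tolerance
#'
#' Precision is the fraction of predicted-boundary pixels strictly closer
#' than `tol` to the ground-truth boundary; recall the converse. An empty
#' predicted boundary gives precision 0, an empty ground-truth boundary
#' recall 0.
#'
#' @param bp,bg predicted / ground-truth [boundary_map]s (coordinate
#'   matrices).
#' @param tol distance tolerance in pixels (strict `<`).
#' @return named numeric vector `c(precision, recall)`.
#' @export
bf_precision_recall <- function(bp, bg, tol) {
  stopifnot(tol > 0)
  precision <- if (nrow(bp) == 0) 0 else mean(min_dists(bp, bg) < tol)
  recall <- if (nrow(bg) == 0) 0 else mean(min_dists(bg, bp) < tol)
  c(precision = precision, recall = recall)
}

#' Default boundary tolerance: 0.75% of the image diagonal
#' @param h,w image height and width in pixels.
#' @return tolerance in pixels (not rounded).
#' @export
bf_default_tol <- function(h, w) 0.0075 * sqrt(h^2 + w^2)

#' Boundary F1 score of one class
#'
#' Harmonic mean of boundary precision and recall for the binary masks
#' `gt == class` and `pred == class`; 0 when precision + recall is 0, `NA`
#' (class skipped) when the class is absent from both masks.
#'
#' @param gt,pred label matrices.
#' @param class 0-based class code.
#' @param tol tolerance in pixels; default 0.75% of the image diagonal.
#' @return rate in `[0, 1]` or `NA`.
#' @export
bfscore <- function(gt, pred, class, tol = bf_default_tol(nrow(gt), ncol(gt))) {
  gm <- gt == class
  pm <- pred == class
  if (!any(gm) && !any(pm)) return(NA_real_)
  pr <- bf_precision_recall(boundary_map(pm), boundary_map(gm), tol)
  if (sum(pr) == 0) return(0)
  unname(2 * pr[1] * pr[2] / (pr[1] + pr[2]))
}

#' Per-image boundary F1: mean of per-class scores over scorable classes
#' @param gt,pred label matrices.
#' @param tol tolerance in pixels.
#' @param n number of classes.
#' @return rate in `[0, 1]`, `NaN` if no class is scorable.
#' @export
image_bfscore <- function(gt, pred, tol = bf_default_tol(nrow(gt), ncol(gt)), n = 4L) {
  scores <- vapply(0:(n - 1), function(o) bfscore(gt, pred, o, tol), numeric(1))
  mean(scores, na.rm = TRUE)
}

#' Dataset boundary F1: mean of per-image scores (not pixel-pooled)
#' @param pairs list of `list(gt =, pred =)` label-matrix pairs.
#' @param tol tolerance in pixels; default derived per image.
#' @param n number of classes.
#' @return rate in `[0, 1]`.
#' @export
dataset_bfscore <- function(pairs, tol = NULL, n = 4L) {
  scores <- vapply(pairs, function(pr) {
    t0 <- if (is.null(tol)) bf_default_tol(nrow(pr$gt), ncol(pr$gt)) else tol
    image_bfscore(pr$gt, pr$pred, t0, n)
  }, numeric(1))
  bad <- is.nan(scores)
  if (any(bad)) message("dataset_bfscore: excluding ", sum(bad),
                        " image(s) with no scorable class")
  mean(scores[!bad])
}

#' Per-image metric report
#'
#' One row per image: global accuracy, mean accuracy, boundary F1, the LGE
#' true-positive pixel count (pred = 3 and gt = 3) and the LGE
#' predicted-positive count (pred = 3).
#'
#' @param pairs list of `list(gt =, pred =)` label-matrix pairs.
#' @param n number of classes.
#' @param tol boundary tolerance; default derived per image.
#' @return `data.frame` with one row per image.
#' @export
per_image_report <- function(pairs, n = 4L, tol = NULL) {
  rows <- lapply(seq_along(pairs), function(i) {
    gt <- pairs[[i]]$gt; pred <- pairs[[i]]$pred
    cm <- confusion_matrix(gt, pred, n)
    t0 <- if (is.null(tol)) bf_default_tol(nrow(gt), ncol(gt)) else tol
    data.frame(image = i,
               gAcc = global_accuracy(cm),
               aAcc = suppressWarnings(mean_accuracy(cm)),
               bfscore = image_bfscore(gt, pred, t0, n),
               lge_tp = sum(gt == 3L & pred == 3L),
               lge_pred = sum(pred == 3L))
  })
  do.call(rbind, rows)
}

#' Full metric report over a set of image pairs
#'
#' Dataset-level metrics from the pooled confusion matrix plus the per-image
#' table of [per_image_report].
#'
#' @param pairs list of `list(gt =, pred =)` label-matrix pairs.
#' @param n number of classes.
#' @return object of class `metrics_report`.
#' @export
metrics_report <- function(pairs, n = 4L) {
  cm <- confusion_matrix(lapply(pairs, `[[`, "gt"), lapply(pairs, `[[`, "pred"), n)
  structure(list(
    confusion = cm,
    gAcc = global_accuracy(cm),
    aAcc = suppressWarnings(mean_accuracy(cm)),
    class_accuracy = class_accuracy(cm),
    class_iou = vapply(0:(n - 1), function(a) class_iou(cm, a), numeric(1)),
    mean_iou = mean_iou(cm),
    wIoU = weighted_iou(cm),
    bfscore = dataset_bfscore(pairs, n = n),
    per_image = per_image_report(pairs, n)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("gAcc %.4f | aAcc %.4f | mean IoU %.4f | wIoU %.4f | bfscore %.4f\n",
              x$gAcc, x$aAcc, x$mean_iou, x$wIoU, x$bfscore))
  cat("per-class accuracy:", sprintf("%.4f", x$class_accuracy), "\n")
  cat("per-class IoU:     ", sprintf("%.4f", x$class_iou), "\n")
  invisible(x)
}
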