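# Evaluation metrics: accuracy, precision/recall, average precision and
# confusion matrices.

#' Confusion counts
#'
#' @param TP,TN,FP,FN nonnegative integer counts (binary or per-class
#'   one-vs-rest).
#' @return list of class `fgr_confusion_counts`.
#' @export
fgr_confusion_counts <- function(TP, TN, FP, FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN),
            class = "fgr_confusion_counts")
}

#' Accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param counts [fgr_confusion_counts()].
#' @return accuracy in [0, 1].
#' @export
fgr_accuracy <- function(counts) {
  tot <- counts$TP + counts$TN + counts$FP + counts$FN
  if (tot <= 0) stop("accuracy undefined on all-zero counts")
  (counts$TP + counts$TN) / tot
}

#' Precision and recall
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`; a zero denominator yields 0 (the
#' documented degenerate convention).
#'
#' @param counts [fgr_confusion_counts()].
#' @return named vector `c(P = , R = )`.
#' @export
fgr_precision_recall <- function(counts) {
  P <- if (counts$TP + counts$FP > 0) counts$TP / (counts$TP + counts$FP) else 0
  R <- if (counts$TP + counts$FN > 0) counts$TP / (counts$TP + counts$FN) else 0
  c(P = P, R = R)
}

# Greedy one-to-one matching of score-sorted predictions to unmatched truth
# boxes of the same class; returns a logical TP flag per prediction (in the
# sorted order) plus the sorted order itself.
match_predictions <- function(preds, truth, iou_thresh) {
  o <- order(-preds$score, preds$x1, preds$y1, seq_len(nrow(preds)))
  used <- rep(FALSE, nrow(truth))
  tp <- logical(nrow(preds))
  for (k in seq_along(o)) {
    i <- o[k]
    cand <- which(!used & truth$class_id == preds$class_id[i])
    if (!length(cand)) next
    ious <- vapply(cand, function(j) {
      fgr_iou(as.list(preds[i, c("x1", "y1", "x2", "y2")]),
              as.list(truth[j, c("x1", "y1", "x2", "y2")]))
    }, 0)
    best <- which.max(ious)
    if (ious[best] >= iou_thresh) {
      tp[k] <- TRUE
      used[cand[best]] <- TRUE
    }
  }
  list(order = o, tp = tp)
}

# All-point-interpolated area under the precision envelope for one class.
ap_one_class <- function(tp, n_truth) {
  if (n_truth == 0L) return(NA_real_)
  if (!length(tp)) return(0)
  ctp <- cumsum(tp)
  cfp <- cumsum(!tp)
  rec <- ctp / n_truth
  prec <- ctp / (ctp + cfp)
  # precision envelope: running max from the right
  env <- rev(cummax(rev(prec)))
  r_prev <- c(0, rec[-length(rec)])
  sum((rec - r_prev) * env)
}

#' Average precision
#'
#' Predictions are sorted by score (descending) and greedily matched
#' one-to-one to unmatched ground-truth boxes of the same class at
#' `IoU >= iou_thresh`; AP is the all-point-interpolated area under the
#' precision envelope over recall, computed per class and macro-averaged.
#' Classes without ground truth are excluded from the mean.
#'
#' @param preds detection data.frame (x1, y1, x2, y2, score, class_id).
#' @param truth ground-truth data.frame (x1, y1, x2, y2, class_id).
#' @param iou_thresh match threshold in (0, 1), default 0.5.
#' @param per_class if `TRUE`, return the per-class vector instead of the
#'   macro mean.
#' @return AP in [0, 1] (or named per-class vector).
#' @export
fgr_average_precision <- function(preds, truth, iou_thresh = 0.5,
                                  per_class = FALSE) {
  stopifnot(iou_thresh > 0, iou_thresh < 1)
  if (nrow(truth) == 0L) stop("AP undefined with no ground truth at all")
  classes <- sort(unique(truth$class_id))
  aps <- vapply(classes, function(cl) {
    tr <- truth[truth$class_id == cl, , drop = FALSE]
    pr <- preds[preds$class_id == cl, , drop = FALSE]
    if (nrow(pr) == 0L) return(0)
    m <- match_predictions(pr, tr, iou_thresh)
    ap_one_class(m$tp, nrow(tr))
  }, 0)
  names(aps) <- classes
  if (per_class) aps else mean(aps)
}

#' Detection precision/recall at a score threshold
#'
#' Counts TP/FP/FN from greedy matching of all predictions (already
#' filtered by any score floor) against ground truth.
#'
#' @inheritParams fgr_average_precision
#' @return list with counts and `P`, `R`.
#' @export
fgr_detection_pr <- function(preds, truth, iou_thresh = 0.5) {
  if (nrow(preds) == 0L) {
    return(list(TP = 0L, FP = 0L, FN = nrow(truth), P = 0, R = 0))
  }
  classes <- unique(c(preds$class_id, truth$class_id))
  TP <- 0L; FP <- 0L; FN <- 0L
  for (cl in classes) {
    pr <- preds[preds$class_id == cl, , drop = FALSE]
    tr <- truth[truth$class_id == cl, , drop = FALSE]
    if (nrow(pr)) {
      m <- match_predictions(pr, tr, iou_thresh)
      TP <- TP + sum(m$tp); FP <- FP + sum(!m$tp)
      FN <- FN + nrow(tr) - sum(m$tp)
    } else FN <- FN + nrow(tr)
  }
  pr <- fgr_precision_recall(fgr_confusion_counts(TP, 0L, FP, FN))
  list(TP = TP, FP = FP, FN = FN, P = unname(pr["P"]), R = unname(pr["R"]))
}

#' Confusion matrix
#'
#' Entry `(i, j)` counts samples of true class `i` predicted as class `j`
#' (0-based ids on both axes); row sums give per-class support.
#'
#' @param pred_classes,true_classes integer vectors of 0-based class ids.
#' @param K number of classes.
#' @return `K x K` integer matrix.
#' @export
fgr_confusion_matrix <- function(pred_classes, true_classes, K) {
  stopifnot(length(pred_classes) == length(true_classes))
  if (length(pred_classes) &&
      (max(pred_classes, true_classes) >= K || min(pred_classes, true_classes) < 0)) {
    stop("class ids must lie in 0..K-1")
  }
  m <- matrix(0L, K, K)
  for (i in seq_along(pred_classes)) {
    r <- true_classes[i] + 1L; c_ <- pred_classes[i] + 1L
    m[r, c_] <- m[r, c_] + 1L
  }
  dimnames(m) <- list(true = 0:(K - 1), pred = 0:(K - 1))
  m
}

#' Render a confusion matrix as an image heat map
#'
#' Row-normalized counts drawn as a grayscale-to-heat grid, written as a
#' binary PPM (runtime artifact).
#'
#' @param cm matrix from [fgr_confusion_matrix()].
#' @param path output path.
#' @param cell pixel size per matrix cell.
#' @return `path` invisibly.
#' @export
fgr_render_confusion <- function(cm, path, cell = 16L) {
  K <- nrow(cm)
  rs <- rowSums(cm)
  norm <- cm / ifelse(rs > 0, rs, 1)
  img <- array(0, c(K * cell, K * cell, 3))
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      v <- norm[i, j]
      rows <- (i - 1L) * cell + seq_len(cell)
      cols <- (j - 1L) * cell + seq_len(cell)
      img[rows, cols, 1] <- v
      img[rows, cols, 2] <- 0.2 + 0.3 * v
      img[rows, cols, 3] <- 1 - v
    }
  }
  fgr_write_ppm(img, path)
  invisible(path)
}
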