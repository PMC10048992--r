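# Training losses: label-smoothed cross-entropy and the CIoU box loss.

#' Label smoothing
#'
#' `y' = (1 - eps) * onehot + eps * mu` with `mu` the uniform distribution
#' `1/K`. Softens the classification target to curb over-confident logits.
#'
#' @param class_index 0-based true class in `0..K-1`.
#' @param eps smoothing factor in [0, 1).
#' @param K number of classes.
#' @return length-`K` probability vector of class `fgr_smoothed_label`.
#' @export
fgr_smooth_labels <- function(class_index, eps, K) {
  if (eps < 0 || eps >= 1) stop("eps must lie in [0, 1)")
  if (class_index < 0 || class_index >= K) stop("class_index out of range")
  y <- rep(eps / K, K)
  y[class_index + 1L] <- y[class_index + 1L] + (1 - eps)
  structure(y, class = "fgr_smoothed_label")
}

#' Cross-entropy loss
#'
#' `-sum(target * log(pred))` with predictions floored at `1e-12` before
#' the log. Zero iff the prediction matches a one-hot target exactly.
#'
#' @param pred_probs predicted probability vector (must sum to 1 within
#'   1e-6).
#' @param target target distribution (e.g. [fgr_smooth_labels()]).
#' @return nonnegative scalar loss.
#' @export
fgr_ce_loss <- function(pred_probs, target) {
  pred_probs <- as.numeric(pred_probs); target <- as.numeric(target)
  if (length(pred_probs) != length(target)) stop("length mismatch")
  if (abs(sum(pred_probs) - 1) > 1e-6 || any(pred_probs < -1e-12)) {
    stop("pred_probs is not a probability distribution")
  }
  -sum(target * log(pmax(pred_probs, 1e-12)))
}

#' Complete-IoU loss
#'
#' `loss = 1 - (IOU - rho^2/c^2 - alpha * v)` where `rho` is the distance
#' between box centers, `c` the diagonal of the minimal enclosing box,
#' `v = (4/pi^2) (arctan(wt/ht) - arctan(wp/hp))^2` the aspect-ratio
#' penalty and `alpha = v / (1 - IOU + v)` its influence factor (`0` when
#' `v = 0`). Zero iff the boxes coincide; reduces to `1 - IoU` whenever the
#' centers coincide and the aspect ratios match.
#'
#' @param pred,target valid boxes (x1, y1, x2, y2).
#' @return scalar loss.
#' @export
fgr_ciou_loss <- function(pred, target) {
  check_box(pred); check_box(target)
  iou <- fgr_iou(pred, target)
  pcx <- (pred[["x1"]] + pred[["x2"]]) / 2
  pcy <- (pred[["y1"]] + pred[["y2"]]) / 2
  tcx <- (target[["x1"]] + target[["x2"]]) / 2
  tcy <- (target[["y1"]] + target[["y2"]]) / 2
  rho2 <- (pcx - tcx)^2 + (pcy - tcy)^2
  ex1 <- min(pred[["x1"]], target[["x1"]]); ex2 <- max(pred[["x2"]], target[["x2"]])
  ey1 <- min(pred[["y1"]], target[["y1"]]); ey2 <- max(pred[["y2"]], target[["y2"]])
  c2 <- (ex2 - ex1)^2 + (ey2 - ey1)^2
  wp <- pred[["x2"]] - pred[["x1"]]; hp <- pred[["y2"]] - pred[["y1"]]
  wt <- target[["x2"]] - target[["x1"]]; ht <- target[["y2"]] - target[["y1"]]
  v <- (4 / pi^2) * (atan(wt / ht) - atan(wp / hp))^2
  alpha <- if (v == 0) 0 else v / (1 - iou + v)
  1 - (iou - rho2 / c2 - alpha * v)
}
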