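# Box geometry, NMS / Soft-NMS and a minimal grid-anchor detection head.
#
# Detections live in a data.frame with columns x1, y1, x2, y2 (corner
# pixels, inclusive real-valued geometry), score in [0, 1] and class_id
# (integer). Both NMS variants run per class; suppression order is by
# current score descending with deterministic tie-breaking
# (score desc, x1, y1, original index).

#' Construct a corner-encoded box
#'
#' @param x1,y1,x2,y2 corner coordinates in pixels with `x2 > x1`,
#'   `y2 > y1`.
#' @return named numeric vector of class `fgr_box`.
#' @export
fgr_box <- function(x1, y1, x2, y2) {
  stopifnot(is.finite(c(x1, y1, x2, y2)))
  if (x2 <= x1 || y2 <= y1) {
    stop("fgr_box: degenerate box (", x1, ",", y1, ",", x2, ",", y2, ")")
  }
  structure(c(x1 = x1, y1 = y1, x2 = x2, y2 = y2), class = "fgr_box")
}

#' Detection table constructor
#'
#' @param boxes matrix or data.frame with columns x1, y1, x2, y2.
#' @param score numeric scores in [0, 1].
#' @param class_id integer class ids.
#' @return data.frame with class `fgr_detections`.
#' @export
fgr_detections <- function(boxes, score, class_id) {
  b <- as.data.frame(boxes)
  names(b)[1:4] <- c("x1", "y1", "x2", "y2")
  stopifnot(all(score >= 0 & score <= 1), all(b$x2 > b$x1), all(b$y2 > b$y1))
  d <- data.frame(b[1:4], score = score, class_id = as.integer(class_id))
  class(d) <- c("fgr_detections", "data.frame")
  d
}

empty_detections <- function() {
  d <- data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                  y2 = numeric(0), score = numeric(0),
                  class_id = integer(0))
  class(d) <- c("fgr_detections", "data.frame")
  d
}

box_area <- function(b) (b[["x2"]] - b[["x1"]]) * (b[["y2"]] - b[["y1"]])

check_box <- function(b) {
  if (b[["x2"]] <= b[["x1"]] || b[["y2"]] <= b[["y1"]]) {
    stop("degenerate (zero-area) box")
  }
  invisible(b)
}

#' Intersection over union of two boxes
#'
#' Intersection extents are clamped at 0 so disjoint boxes score exactly 0;
#' the result is symmetric and lies in [0, 1].
#'
#' @param a,b boxes: [fgr_box()] or any named vector/list with x1, y1, x2,
#'   y2.
#' @return IoU in [0, 1].
#' @export
fgr_iou <- function(a, b) {
  check_box(a); check_box(b)
  iw <- max(0, min(a[["x2"]], b[["x2"]]) - max(a[["x1"]], b[["x1"]]))
  ih <- max(0, min(a[["y2"]], b[["y2"]]) - max(a[["y1"]], b[["y1"]]))
  s1 <- iw * ih
  s2 <- box_area(a) + box_area(b) - s1
  s1 / s2
}

# Vectorized IoU of one box (length-4 numeric) against a 4-col matrix.
iou_one_many <- function(a, m) {
  iw <- pmax(0, pmin(a[3L], m[, 3L]) - pmax(a[1L], m[, 1L]))
  ih <- pmax(0, pmin(a[4L], m[, 4L]) - pmax(a[2L], m[, 2L]))
  s1 <- iw * ih
  area_a <- (a[3L] - a[1L]) * (a[4L] - a[2L])
  area_m <- (m[, 3L] - m[, 1L]) * (m[, 4L] - m[, 2L])
  s1 / (area_a + area_m - s1)
}

# Deterministic processing order: score desc, then x1, y1, original index.
det_order <- function(d) order(-d$score, d$x1, d$y1, seq_len(nrow(d)))

nms_one_class <- function(d, Nt, soft, score_floor) {
  n <- nrow(d)
  if (n == 0L) return(d)
  boxes <- as.matrix(d[, c("x1", "y1", "x2", "y2")])
  scores <- d$score
  orig <- seq_len(n)
  keep_idx <- integer(0); keep_score <- numeric(0)
  alive <- rep(TRUE, n)
  while (any(alive)) {
    cand <- which(alive)
    cs <- scores[cand]
    o <- order(-cs, d$x1[cand], d$y1[cand], cand)
    m <- cand[o[1L]]
    alive[m] <- FALSE
    if (scores[m] >= score_floor) {
      keep_idx <- c(keep_idx, m); keep_score <- c(keep_score, scores[m])
    } else next
    rest <- which(alive)
    if (!length(rest)) break
    ov <- iou_one_many(boxes[m, ], boxes[rest, , drop = FALSE])
    hit <- ov >= Nt
    if (soft) {
      scores[rest[hit]] <- scores[rest[hit]] * (1 - ov[hit])
      dead <- rest[scores[rest] < score_floor]
      alive[dead] <- FALSE
    } else {
      alive[rest[hit]] <- FALSE
    }
  }
  out <- d[keep_idx, , drop = FALSE]
  out$score <- keep_score
  out
}

#' Hard non-maximum suppression
#'
#' Greedy per-class suppression: repeatedly keep the highest-scoring
#' remaining box and remove every remaining box of the same class whose
#' IoU with it is `>= Nt`.
#'
#' @param dets [fgr_detections()] table (may be empty).
#' @param Nt overlap threshold in (0, 1).
#' @param score_floor boxes below this score are dropped (default 0).
#' @return kept detections, ordered by score descending within class pass.
#' @export
fgr_hard_nms <- function(dets, Nt = 0.5, score_floor = 0) {
  stopifnot(Nt > 0, Nt < 1)
  if (nrow(dets) == 0L) return(dets)
  parts <- lapply(split(seq_len(nrow(dets)), dets$class_id), function(ix) {
    nms_one_class(dets[ix, , drop = FALSE], Nt, soft = FALSE,
                  score_floor = score_floor)
  })
  out <- do.call(rbind, parts)
  out <- out[det_order(out), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fgr_detections", "data.frame")
  out
}

#' Soft non-maximum suppression (linear decay)
#'
#' Like hard NMS, but instead of removing overlapping boxes their scores
#' decay: a remaining box `b_i` with `IOU(M, b_i) >= Nt` against the
#' current top box `M` is rescored `S_i * (1 - IOU(M, b_i))`; boxes with
#' overlap below `Nt` keep their score. Iteration continues over remaining
#' boxes by current descending score; boxes whose decayed score falls below
#' `score_floor` are dropped. Applied per class. Needs no training and
#' never increases a score.
#'
#' @inheritParams fgr_hard_nms
#' @param score_floor minimum surviving score, in [0, 1).
#' @return rescored kept detections.
#' @export
fgr_soft_nms <- function(dets, Nt = 0.5, score_floor = 0.001) {
  stopifnot(Nt > 0, Nt < 1, score_floor >= 0, score_floor < 1)
  if (nrow(dets) == 0L) return(dets)
  parts <- lapply(split(seq_len(nrow(dets)), dets$class_id), function(ix) {
    nms_one_class(dets[ix, , drop = FALSE], Nt, soft = TRUE,
                  score_floor = score_floor)
  })
  out <- do.call(rbind, parts)
  out <- out[det_order(out), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fgr_detections", "data.frame")
  out
}

# ---- minimal grid-anchor detection head --------------------------------

#' Initialize a detection head
#'
#' A 1x1 convolution over a backbone feature map producing, per grid cell
#' and anchor, `(tx, ty, tw, th, obj, cls_1..cls_K)` activations.
#'
#' @param in_channels feature channels of the tapped stage.
#' @param anchors list/matrix of anchor `(w, h)` pairs in pixels.
#' @param n_classes number of object classes.
#' @param seed RNG seed for the weight draw.
#' @return head parameter list.
#' @export
fgr_detection_head_init <- function(in_channels, anchors, n_classes,
                                    seed = NULL) {
  anchors <- matrix(unlist(anchors), ncol = 2L, byrow = !is.matrix(anchors))
  stopifnot(nrow(anchors) >= 1L, all(anchors > 0))
  nA <- nrow(anchors)
  per <- 5L + n_classes
  with_seed(seed, {
    list(W = he_conv(1L, 1L, in_channels, nA * per) * 0.1,
         b = rep(0, nA * per),
         anchors = anchors, n_classes = as.integer(n_classes))
  })
}

# Decode raw activations at one cell/anchor into an image-space box.
# Box center = (cell + sigmoid(txy)) * stride;
# size = anchor * exp(8 tanh(twh / 8)). The tanh saturates the size
# smoothly: a hard clamp leaves a dead zone where finite-difference
# gradients vanish and training freezes, and no clamp at all lets sizes
# overflow or underflow to zero-width boxes.
decode_box <- function(t_xywh, cell_rc, anchor, stride) {
  cx <- (cell_rc[2L] + fgr_sigmoid(t_xywh[1L])) * stride
  cy <- (cell_rc[1L] + fgr_sigmoid(t_xywh[2L])) * stride
  w <- anchor[1L] * exp(8 * tanh(t_xywh[3L] / 8))
  h <- anchor[2L] * exp(8 * tanh(t_xywh[4L] / 8))
  c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}

# Inverse of decode_box; box is c(x1,y1,x2,y2).
encode_box <- function(box, cell_rc, anchor, stride) {
  cx <- (box[1L] + box[3L]) / 2; cy <- (box[2L] + box[4L]) / 2
  w <- box[3L] - box[1L]; h <- box[4L] - box[2L]
  fx <- cx / stride - cell_rc[2L]; fy <- cy / stride - cell_rc[1L]
  eps <- 1e-7
  fx <- min(max(fx, eps), 1 - eps); fy <- min(max(fy, eps), 1 - eps)
  lw <- min(max(log(w / anchor[1L]) / 8, -1 + eps), 1 - eps)
  lh <- min(max(log(h / anchor[2L]) / 8, -1 + eps), 1 - eps)
  c(log(fx / (1 - fx)), log(fy / (1 - fy)), 8 * atanh(lw), 8 * atanh(lh))
}

#' Decode a detection head's raw output grid
#'
#' Runs the 1x1 head convolution over `features` and decodes every cell and
#' anchor into an image-space detection with
#' `score = sigmoid(obj) * max_class softmax(cls)`. With all-zero
#' activations every score is `0.5 * 1/K` and boxes sit centered on their
#' cells at anchor size.
#'
#' @param features `fgr_feature_map` from the tapped backbone stage.
#' @param head head parameters from [fgr_detection_head_init()].
#' @param stride pixels per grid cell (image size / grid size).
#' @return [fgr_detections()] with `S*S*A` rows plus a `cell` bookkeeping
#'   attribute used by training.
#' @export
fgr_detection_head <- function(features, head, stride) {
  raw <- fgr_conv2d(unclass(features), head$W, head$b)
  decode_grid(raw, head, stride)
}

decode_grid <- function(raw, head, stride) {
  gh <- dim(raw)[1L]; gw <- dim(raw)[2L]
  nA <- nrow(head$anchors); K <- head$n_classes; per <- 5L + K
  n <- gh * gw * nA
  out <- matrix(0, n, 4L); sc <- numeric(n); cl <- integer(n)
  cell_r <- integer(n); cell_c <- integer(n); anch <- integer(n)
  k <- 0L
  for (a in seq_len(nA)) {
    off <- (a - 1L) * per
    for (j in seq_len(gw)) {
      for (i in seq_len(gh)) {
        v <- raw[i, j, off + seq_len(per)]
        k <- k + 1L
        out[k, ] <- decode_box(v[1:4], c(i - 1L, j - 1L), head$anchors[a, ],
                               stride)
        p <- fgr_softmax(v[5L + seq_len(K)])
        cl[k] <- which.max(p) - 1L
        sc[k] <- fgr_sigmoid(v[5L]) * max(p)
        cell_r[k] <- i; cell_c[k] <- j; anch[k] <- a
      }
    }
  }
  # guard against degenerate decoded extents (exp clamp keeps them > 0)
  d <- fgr_detections(out, pmin(pmax(sc, 0), 1), cl)
  attr(d, "cells") <- data.frame(row = cell_r, col = cell_c, anchor = anch)
  d
}

# ---- YOLO-format label I/O ---------------------------------------------

#' Read / write YOLO-format label files
#'
#' One line per object: `class cx cy w h` (normalized to [0, 1]) with an
#' optional trailing score column for prediction files.
#'
#' @param path label file path.
#' @param image_size `c(width, height)` in pixels used to convert to corner
#'   boxes.
#' @return `fgr_read_yolo` returns a data.frame with columns class_id, x1,
#'   y1, x2, y2 (+ score if present); an empty/missing file yields zero
#'   rows.
#' @export
fgr_read_yolo <- function(path, image_size) {
  if (!file.exists(path) || file.size(path) == 0) {
    return(data.frame(class_id = integer(0), x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0)))
  }
  m <- as.matrix(utils::read.table(path))
  W <- image_size[1L]; H <- image_size[2L]
  cx <- m[, 2L] * W; cy <- m[, 3L] * H; w <- m[, 4L] * W; h <- m[, 5L] * H
  out <- data.frame(class_id = as.integer(m[, 1L]),
                    x1 = cx - w / 2, y1 = cy - h / 2,
                    x2 = cx + w / 2, y2 = cy + h / 2)
  if (ncol(m) >= 6L) out$score <- m[, 6L]
  out
}

#' @rdname fgr_read_yolo
#' @param boxes data.frame with class_id, x1, y1, x2, y2 and optional score.
#' @export
fgr_write_yolo <- function(boxes, path, image_size) {
  W <- image_size[1L]; H <- image_size[2L]
  lines <- character(nrow(boxes))
  has_score <- "score" %in% names(boxes)
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    cx <- (b$x1 + b$x2) / 2 / W; cy <- (b$y1 + b$y2) / 2 / H
    w <- (b$x2 - b$x1) / W; h <- (b$y2 - b$y1) / H
    vals <- sprintf("%.6f", c(cx, cy, w, h))
    lines[i] <- paste(c(b$class_id, vals,
                        if (has_score) sprintf("%.6f", b$score)),
                      collapse = " ")
  }
  writeLines(lines, path)
  invisible(path)
}
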