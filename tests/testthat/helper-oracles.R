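# Independent brute-force oracles. Everything here is written as plain
# loops straight from the defining formulas, deliberately sharing no code
# with the implementation under test.

# 2-D convolution by explicit quadruple loop.
conv2d_ref <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Cout <- dim(w)[4]
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, Cin))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  oh <- (H + 2 * pad - kh) %/% stride + 1L
  ow <- (W + 2 * pad - kw) %/% stride + 1L
  y <- array(0, c(oh, ow, Cout))
  for (oi in seq_len(oh)) for (oj in seq_len(ow)) for (co in seq_len(Cout)) {
    s <- if (is.null(b)) 0 else b[co]
    for (di in seq_len(kh)) for (dj in seq_len(kw)) for (ci in seq_len(Cin)) {
      s <- s + xp[(oi - 1) * stride + di, (oj - 1) * stride + dj, ci] *
        w[di, dj, ci, co]
    }
    y[oi, oj, co] <- s
  }
  y
}

# Bilinear pooling: explicit loop over positions and channel pairs.
bilinear_ref <- function(xa, xb) {
  H <- dim(xa)[1]; W <- dim(xa)[2]
  CA <- dim(xa)[3]; CB <- dim(xb)[3]
  M <- matrix(0, CA, CB)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    for (a in seq_len(CA)) for (b in seq_len(CB)) {
      M[a, b] <- M[a, b] + xa[i, j, a] * xb[i, j, b]
    }
  }
  as.vector(M / (H * W))
}

# Elementwise softmax of a vector by definition.
softmax_ref <- function(v) exp(v) / sum(exp(v))

# Cross-channel relation by loops: R_raw then signed sqrt then row softmax.
relation_ref <- function(x, phi) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  R <- matrix(0, C, C)
  for (a in seq_len(C)) for (b in seq_len(C)) {
    s <- 0
    for (i in seq_len(H)) for (j in seq_len(W)) s <- s + x[i, j, a] * phi[i, j, b]
    R[a, b] <- s / (W * H)
  }
  M <- matrix(0, C, C)
  for (a in seq_len(C)) for (b in seq_len(C)) {
    M[a, b] <- sign(R[a, b]) * sqrt(abs(R[a, b]))
  }
  for (a in seq_len(C)) M[a, ] <- softmax_ref(M[a, ])
  M
}

# Trilinear attention maps by loops.
trilinear_ref <- function(fc, phi) {
  H <- dim(phi)[1]; W <- dim(phi)[2]; C <- dim(phi)[3]
  out <- array(0, c(C, H, W))
  for (r in seq_len(C)) {
    v <- numeric(H * W)
    k <- 0
    for (j in seq_len(W)) for (i in seq_len(H)) {
      k <- k + 1
      s <- 0
      for (c_ in seq_len(C)) s <- s + fc[c_, r] * phi[i, j, c_]
      v[k] <- sign(s) * sqrt(abs(s))
    }
    v <- softmax_ref(v)
    out[r, , ] <- matrix(v, H, W)
  }
  out
}

# Graph propagation by dense loops.
propagate_ref <- function(K, A_tilde, W) {
  N <- nrow(K)
  deg <- numeric(N)
  for (i in seq_len(N)) deg[i] <- sum(A_tilde[i, ])
  Sm <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    Sm[i, j] <- A_tilde[i, j] / sqrt(deg[i] * deg[j])
  }
  pre <- Sm %*% K %*% W
  pmax(pre, 0)
}

# scalar IoU of two boxes given as numeric vectors c(x1, y1, x2, y2),
# straight from the area formulas
iou_ref_v <- function(a, b) {
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw < 0) iw <- 0
  if (ih < 0) ih <- 0
  s1 <- iw * ih
  s2 <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - s1
  s1 / s2
}

# list/data.frame-friendly wrapper
iou_ref <- function(a, b) {
  iou_ref_v(c(a$x1, a$y1, a$x2, a$y2), c(b$x1, b$y1, b$x2, b$y2))
}

# Hard NMS reference: O(n^2) loop per class over plain vectors.
hard_nms_ref <- function(d, Nt) {
  B <- cbind(d$x1, d$y1, d$x2, d$y2)
  keep <- integer(0)
  for (cl in unique(d$class_id)) {
    idx <- which(d$class_id == cl)
    idx <- idx[order(-d$score[idx], d$x1[idx], d$y1[idx])]
    alive <- rep(TRUE, length(idx))
    for (i in seq_along(idx)) {
      if (!alive[i]) next
      keep <- c(keep, idx[i])
      for (j in seq_along(idx)) {
        if (j <= i || !alive[j]) next
        if (iou_ref_v(B[idx[i], ], B[idx[j], ]) >= Nt) alive[j] <- FALSE
      }
    }
  }
  out <- d[keep, , drop = FALSE]
  out[order(-out$score, out$x1, out$y1), , drop = FALSE]
}

# Soft NMS reference with an arbitrary decay factor function of the
# overlap (linear decay by default; `function(ov) 0` zeroes like hard
# NMS).
soft_nms_ref <- function(d, Nt, floor, decay = function(ov) 1 - ov) {
  B <- cbind(d$x1, d$y1, d$x2, d$y2)
  keep <- integer(0); kscore <- numeric(0)
  for (cl in unique(d$class_id)) {
    idx <- which(d$class_id == cl)
    scores <- d$score
    alive <- rep(TRUE, nrow(d)); alive[-idx] <- FALSE
    repeat {
      cand <- which(alive)
      if (!length(cand)) break
      m <- cand[order(-scores[cand], d$x1[cand], d$y1[cand])][1]
      alive[m] <- FALSE
      if (scores[m] < floor) next
      keep <- c(keep, m); kscore <- c(kscore, scores[m])
      for (j in which(alive)) {
        ov <- iou_ref_v(B[m, ], B[j, ])
        if (ov >= Nt) scores[j] <- scores[j] * decay(ov)
        if (scores[j] < floor) alive[j] <- FALSE
      }
    }
  }
  out <- d[keep, , drop = FALSE]
  out$score <- kscore
  out[order(-out$score, out$x1, out$y1), , drop = FALSE]
}

# CIoU loss evaluated step by step from the defining equations.
ciou_ref <- function(p, t) {
  iou <- iou_ref(p, t)
  rho2 <- ((p$x1 + p$x2) / 2 - (t$x1 + t$x2) / 2)^2 +
    ((p$y1 + p$y2) / 2 - (t$y1 + t$y2) / 2)^2
  cx <- max(p$x2, t$x2) - min(p$x1, t$x1)
  cy <- max(p$y2, t$y2) - min(p$y1, t$y1)
  c2 <- cx^2 + cy^2
  v <- 4 / pi^2 *
    (atan((t$x2 - t$x1) / (t$y2 - t$y1)) -
       atan((p$x2 - p$x1) / (p$y2 - p$y1)))^2
  alpha <- if (v == 0) 0 else v / (1 - iou + v)
  1 - (iou - rho2 / c2 - alpha * v)
}

# Average precision by exhaustive prefix thresholds: for every prefix of
# the score-sorted prediction list compute (recall, precision); integrate
# the running-max precision envelope over recall.
ap_ref <- function(preds, truth, iou_thresh) {
  classes <- sort(unique(truth$class_id))
  aps <- numeric(0)
  for (cl in classes) {
    tr <- truth[truth$class_id == cl, , drop = FALSE]
    pr <- preds[preds$class_id == cl, , drop = FALSE]
    if (nrow(pr) == 0) { aps <- c(aps, 0); next }
    pr <- pr[order(-pr$score, pr$x1, pr$y1), , drop = FALSE]
    used <- rep(FALSE, nrow(tr))
    tp <- logical(nrow(pr))
    for (i in seq_len(nrow(pr))) {
      best <- 0; bj <- 0
      for (j in seq_len(nrow(tr))) {
        if (used[j]) next
        ov <- iou_ref(pr[i, ], tr[j, ])
        if (ov > best) { best <- ov; bj <- j }
      }
      if (bj > 0 && best >= iou_thresh) { tp[i] <- TRUE; used[bj] <- TRUE }
    }
    rec <- numeric(nrow(pr)); prec <- numeric(nrow(pr))
    for (k in seq_len(nrow(pr))) {
      rec[k] <- sum(tp[1:k]) / nrow(tr)
      prec[k] <- sum(tp[1:k]) / k
    }
    ap <- 0
    prev_r <- 0
    for (k in seq_len(nrow(pr))) {
      env <- max(prec[k:length(prec)])
      ap <- ap + (rec[k] - prev_r) * env
      prev_r <- rec[k]
    }
    aps <- c(aps, ap)
  }
  mean(aps)
}

# random valid detections table
random_dets <- function(n, n_classes = 2L, size = 100) {
  x1 <- runif(n, 0, size * 0.8); y1 <- runif(n, 0, size * 0.8)
  w <- runif(n, 4, size * 0.3); h <- runif(n, 4, size * 0.3)
  fgr_detections(data.frame(x1 = x1, y1 = y1, x2 = x1 + w, y2 = y1 + h),
                 score = runif(n, 0.05, 1),
                 class_id = sample.int(n_classes, n, replace = TRUE) - 1L)
}
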