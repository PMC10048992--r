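# The full fine-grained classifier: CSP backbone -> CTA attention pyramid
# -> graph embedding per level -> adaptive level fusion.
#
# Training strategy (a deliberate CPU-scale choice, see the methods
# vignette): the backbone, phi and tau convolutions stay frozen at their
# seeded random initialization and act as a deterministic feature
# extractor; gradient descent trains the graph projections W_m, the
# per-level classifier heads and the adaptive level-attention parameters
# with exact analytic backpropagation. Random convolutional features plus
# a trained high-order embedding are enough for the toy-scale worlds this
# package targets, and keep every documented budget on one CPU.

model_levels <- c("trunk", "level2", "level3", "level4")

#' Construct a fine-grained recognition model
#'
#' @param n_classes number of classes (>= 2).
#' @param stages list of [fgr_stage_config()]s (default
#'   [fgr_default_stages()]).
#' @param Dh graph embedding width.
#' @param max_nodes cap on graph nodes per level.
#' @param tau_dim width of the frozen similarity transform tau.
#' @param seed seed fixing every parameter draw.
#' @return model object (class `fgr_model`): nested named parameter list.
#' @export
fgr_model <- function(n_classes, stages = fgr_default_stages(), Dh = 32L,
                      max_nodes = 32L, tau_dim = 16L, seed = 1L) {
  stopifnot(n_classes >= 2L)
  widths <- vapply(stages, function(s) s$out_channels, 0L)
  backbone <- init_backbone(stages, child_seed(seed, "backbone"))
  dims <- c(trunk = widths[length(widths)], level2 = widths[2L],
            level3 = widths[3L], level4 = widths[4L])
  gfe <- with_seed(child_seed(seed, "gfe"), {
    lapply(stats::setNames(model_levels, model_levels), function(lv) {
      D <- dims[[lv]]
      list(tau = matrix(stats::rnorm(D * tau_dim, sd = 1 / sqrt(D)), D, tau_dim),
           W = matrix(stats::rnorm(D * Dh, sd = sqrt(2 / D)), D, Dh),
           att_w = stats::rnorm(Dh, sd = 0.1), att_b = 0,
           head_W = matrix(0, Dh, n_classes),
           head_b = rep(0, n_classes))
    })
  })
  structure(list(n_classes = as.integer(n_classes), stages = stages,
                 Dh = as.integer(Dh), max_nodes = as.integer(max_nodes),
                 tau_dim = as.integer(tau_dim), seed = as.integer(seed),
                 backbone = backbone, gfe = gfe),
            class = "fgr_model")
}

# Average-pool a feature map onto a g x g grid of nodes (g^2 x C).
avgpool_nodes <- function(feat, g = 4L) {
  d <- dim(feat)
  bh <- d[1L] %/% g; bw <- d[2L] %/% g
  nodes <- matrix(0, g * g, d[3L])
  k <- 0L
  for (j in seq_len(g)) {
    for (i in seq_len(g)) {
      k <- k + 1L
      blk <- unclass(feat)[(i - 1L) * bh + seq_len(bh),
                           (j - 1L) * bw + seq_len(bw), , drop = FALSE]
      nodes[k, ] <- apply(blk, 3L, mean)
    }
  }
  nodes
}

# Propagated bank S~ K for one part bank under the model's frozen tau.
propagated_bank <- function(bank, tau) {
  a_tilde <- fgr_adjacency(bank, tau, nonneg = TRUE)
  deg <- rowSums(a_tilde)
  dm <- 1 / sqrt(deg)
  (a_tilde * outer(dm, dm)) %*% bank$nodes
}

#' Extract per-image features for training and inference
#'
#' Runs the frozen backbone + CTA pyramid once and returns everything the
#' trainable stack and the ablation variants need:
#' \itemize{
#'   \item `M` — per level (trunk, 2, 3, 4), the propagated node bank
#'     `D^(-1/2) A~ D^(-1/2) K` that the trainable projection multiplies;
#'   \item `M_uniform` — same, but with uniform-grid nodes (no CTA), for
#'     the +GFE-only ablation;
#'   \item `gap` — stage-4 global-average-pooled vector (backbone+GAP
#'     ablation);
#'   \item `cta` — concatenated per-level means of the attention-pooled
#'     banks (+CTA-only ablation).
#' }
#'
#' @param model [fgr_model()].
#' @param image `H x W x 3` array.
#' @return feature list.
#' @export
fgr_extract_features <- function(model, image) {
  stages <- fgr_backbone_forward(image, model$backbone, resize = TRUE,
                                 all_stages = TRUE)
  pyr <- fgr_attention_pyramid(stages, model$backbone)
  banks <- list(trunk = fgr_part_bank(avgpool_nodes(stages$stage4, 4L), 0L))
  for (i in 1:3) {
    att <- pyr[[i]]
    feat <- stages[[paste0("stage", att$level)]]
    banks[[paste0("level", att$level)]] <-
      fgr_part_pooling(att, feat, model$max_nodes)
  }
  ubanks <- list(trunk = banks$trunk)
  for (lv in 2:4) {
    ubanks[[paste0("level", lv)]] <-
      fgr_part_bank(avgpool_nodes(stages[[paste0("stage", lv)]], 4L), lv)
  }
  M <- lapply(stats::setNames(model_levels, model_levels), function(lv) {
    propagated_bank(banks[[lv]], model$gfe[[lv]]$tau)
  })
  Mu <- lapply(stats::setNames(model_levels, model_levels), function(lv) {
    propagated_bank(ubanks[[lv]], model$gfe[[lv]]$tau)
  })
  gap <- apply(unclass(stages$stage4), 3L, mean)
  cta <- unlist(lapply(model_levels[-1L], function(lv) {
    colMeans(banks[[lv]]$nodes)
  }))
  list(M = M, M_uniform = Mu, gap = gap, cta = cta)
}

# Forward pass of the trainable stack on one feature set.
# Returns the fused probability vector plus intermediates for backprop.
gfe_forward <- function(gfe, M_list, keep = FALSE) {
  lv <- names(M_list)
  G <- list(); g <- list(); z <- list(); p <- list(); u <- list()
  eta <- numeric(length(lv))
  for (m in seq_along(lv)) {
    pr <- gfe[[lv[m]]]
    Pre <- M_list[[m]] %*% pr$W
    Gm <- relu(Pre)
    gm <- colMeans(Gm)
    zm <- drop(gm %*% pr$head_W + pr$head_b)
    um <- drop(Gm %*% pr$att_w + pr$att_b)
    eta[m] <- mean(tanh(um))
    G[[m]] <- Gm; g[[m]] <- gm; z[[m]] <- zm; u[[m]] <- um
    p[[m]] <- fgr_softmax(zm)
  }
  I <- fgr_softmax(eta)
  C <- Reduce(`+`, Map(function(Im, pm) Im * pm, as.list(I), p))
  if (!keep) return(C)
  list(C = C, I = I, eta = eta, G = G, g = g, z = z, p = p, u = u)
}

#' Predict class probabilities for one image
#'
#' @param model trained [fgr_model()].
#' @param image `H x W x 3` array, or a cached feature list from
#'   [fgr_extract_features()].
#' @return fused probability vector over classes.
#' @export
fgr_predict <- function(model, image) {
  feats <- if (is.list(image) && !is.null(image$M)) image
           else fgr_extract_features(model, image)
  gfe_forward(model$gfe, apply_bank_stats(feats$M, model$bank_stats))
}

# Per-entry standardization statistics of the cached node banks over a
# training set; the same affine preprocessing is applied at inference
# (stored on the trained model). Purely a conditioning step for SGD.
bank_stats <- function(feats, slot) {
  lv <- names(feats[[1L]][[slot]])
  stats::setNames(lapply(lv, function(l) {
    mats <- lapply(feats, function(f) f[[slot]][[l]])
    d <- dim(mats[[1L]])
    V <- vapply(mats, as.vector, numeric(prod(d)))
    mu <- rowMeans(V)
    sdv <- pmax(sqrt(rowMeans(V^2) - mu^2), 1e-6)
    list(mu = array(mu, d), sd = array(sdv, d))
  }), lv)
}

apply_bank_stats <- function(M_list, stats) {
  if (is.null(stats)) return(M_list)
  stats::setNames(lapply(names(M_list), function(l) {
    (M_list[[l]] - stats[[l]]$mu) / stats[[l]]$sd
  }), names(M_list))
}

# Cosine-annealed learning rate: restarts every `period` epochs,
# nonincreasing within each period.
cosine_lr <- function(epoch, lr0, period, lr_min = lr0 * 0.01) {
  t <- (epoch - 1) %% period
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * t / period))
}

# One backprop pass for a single sample; returns loss and gradients
# (same shape as the trainable slots of gfe).
gfe_backward <- function(gfe, M_list, target) {
  fw <- gfe_forward(gfe, M_list, keep = TRUE)
  lv <- names(M_list)
  Cc <- pmax(fw$C, 1e-12)
  loss <- -sum(target * log(Cc))
  dC <- -target / Cc
  dI <- vapply(fw$p, function(pm) sum(dC * pm), 0)
  deta <- fw$I * (dI - sum(dI * fw$I))
  grads <- list()
  for (m in seq_along(lv)) {
    pr <- gfe[[lv[m]]]
    G <- fw$G[[m]]; N <- nrow(G)
    dp <- fw$I[m] * dC
    pm <- fw$p[[m]]
    dz <- pm * (dp - sum(dp * pm))
    g_headW <- outer(fw$g[[m]], dz)
    g_headb <- dz
    dg <- drop(pr$head_W %*% dz)
    th <- tanh(fw$u[[m]])
    du <- deta[m] * (1 - th^2) / N
    g_attw <- drop(crossprod(G, du))
    g_attb <- sum(du)
    dG <- outer(du, pr$att_w) + matrix(dg, N, length(dg), byrow = TRUE) / N
    dPre <- dG * (G > 0)
    g_W <- crossprod(M_list[[m]], dPre)
    grads[[lv[m]]] <- list(W = g_W, head_W = g_headW, head_b = g_headb,
                           att_w = g_attw, att_b = g_attb)
  }
  list(loss = loss, grads = grads, C = fw$C)
}

trainable_slots <- c("W", "head_W", "head_b", "att_w", "att_b")

#' Train the graph-embedding stack on cached features
#'
#' SGD with momentum and cosine-annealed learning rate over the trainable
#' parameters (graph projections, heads, level attention), with
#' label-smoothed cross-entropy on the fused score. Aborts with a
#' diagnostic if the loss diverges to NaN.
#'
#' @param gfe trainable parameter set (`model$gfe`).
#' @param feats_train list of per-sample feature lists (each with `M`).
#' @param y_train 0-based labels.
#' @param K number of classes.
#' @param feats_val,y_val optional validation set for per-epoch ACC.
#' @param epochs,batch_size,lr,momentum,period,eps training
#'   hyperparameters (`period` = cosine annealing restart period in
#'   epochs, `eps` = label smoothing).
#' @param weight_decay L2 penalty coefficient on the weight matrices
#'   (biases exempt).
#' @param seed shuffling seed.
#' @param slot which cached bank to train on (`"M"` or `"M_uniform"`).
#' @param verbose print per-epoch log lines.
#' @return list: trained `gfe`, per-epoch `log` data.frame, `best_acc`,
#'   best-epoch parameter snapshot.
#' @export
fgr_train_gfe <- function(gfe, feats_train, y_train, K,
                          feats_val = NULL, y_val = NULL,
                          epochs = 60L, batch_size = 16L, lr = 0.25,
                          momentum = 0.9, period = 20L, eps = 0.1,
                          seed = 1L, slot = "M", standardize = TRUE,
                          weight_decay = 1e-4, verbose = FALSE) {
  n <- length(feats_train)
  targets <- lapply(y_train, function(yy) {
    as.numeric(fgr_smooth_labels(yy, eps, K))
  })
  stats <- if (standardize) bank_stats(feats_train, slot) else NULL
  M_train <- lapply(feats_train, function(f) apply_bank_stats(f[[slot]], stats))
  M_val <- if (!is.null(feats_val)) {
    lapply(feats_val, function(f) apply_bank_stats(f[[slot]], stats))
  }
  vel <- lapply(gfe, function(pr) {
    lapply(pr[trainable_slots], function(x) x * 0)
  })
  log_rows <- list()
  best <- list(acc = -1, gfe = gfe)
  for (ep in seq_len(epochs)) {
    lr_t <- cosine_lr(ep, lr, period)
    ord <- with_seed(child_seed(seed, paste0("ep", ep)), sample.int(n))
    ep_loss <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      acc_g <- NULL
      for (i in idx) {
        bw <- gfe_backward(gfe, M_train[[i]], targets[[i]])
        if (!is.finite(bw$loss)) {
          stop("training diverged: non-finite loss at epoch ", ep,
               " sample ", i)
        }
        ep_loss <- ep_loss + bw$loss
        if (is.null(acc_g)) acc_g <- bw$grads
        else for (lvn in names(acc_g)) for (s in trainable_slots) {
          acc_g[[lvn]][[s]] <- acc_g[[lvn]][[s]] + bw$grads[[lvn]][[s]]
        }
      }
      nb <- length(idx)
      wd_slots <- c("W", "head_W", "att_w")
      for (lvn in names(gfe)) for (s in trainable_slots) {
        g <- acc_g[[lvn]][[s]] / nb
        if (s %in% wd_slots) g <- g + weight_decay * gfe[[lvn]][[s]]
        vel[[lvn]][[s]] <- momentum * vel[[lvn]][[s]] - lr_t * g
        gfe[[lvn]][[s]] <- gfe[[lvn]][[s]] + vel[[lvn]][[s]]
      }
    }
    ep_loss <- ep_loss / n
    acc <- NA_real_
    if (!is.null(feats_val)) {
      pred <- vapply(M_val, function(Mv) {
        which.max(gfe_forward(gfe, Mv)) - 1L
      }, 0L)
      acc <- mean(pred == y_val)
      if (acc >= best$acc) best <- list(acc = acc, gfe = gfe)
    }
    log_rows[[ep]] <- data.frame(epoch = ep, lr = lr_t, loss = ep_loss,
                                 val_acc = acc)
    if (verbose) {
      message(sprintf("epoch %3d  lr %.4f  loss %.4f  val_acc %s",
                      ep, lr_t, ep_loss,
                      ifelse(is.na(acc), "-", sprintf("%.3f", acc))))
    }
  }
  if (is.null(feats_val)) best <- list(acc = NA_real_, gfe = gfe)
  list(gfe = gfe, log = do.call(rbind, log_rows), best_acc = best$acc,
       best_gfe = best$gfe, stats = stats)
}

#' Train a plain linear softmax classifier on fixed feature vectors
#'
#' Used by the ablation harness for the backbone+GAP and +CTA variants.
#' Same optimizer (SGD + momentum + cosine annealing) and label-smoothed
#' cross-entropy as the full stack.
#'
#' @param X `n x D` feature matrix.
#' @param y 0-based labels.
#' @param K classes.
#' @inheritParams fgr_train_gfe
#' @param X_val,y_val optional validation data.
#' @return list with `W`, `b`, `log`, `best_acc`.
#' @export
fgr_train_linear <- function(X, y, K, X_val = NULL, y_val = NULL,
                             epochs = 60L, batch_size = 16L, lr = 0.25,
                             momentum = 0.9, period = 20L, eps = 0.1,
                             seed = 1L) {
  n <- nrow(X); D <- ncol(X)
  mu <- colMeans(X); sdv <- pmax(apply(X, 2L, stats::sd), 1e-6)
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, `/`)
  Tm <- t(vapply(y, function(yy) as.numeric(fgr_smooth_labels(yy, eps, K)),
                 numeric(K)))
  W <- matrix(0, D, K); b <- rep(0, K)
  vW <- W; vb <- b
  best <- list(acc = -1, W = W, b = b)
  log_rows <- list()
  for (ep in seq_len(epochs)) {
    lr_t <- cosine_lr(ep, lr, period)
    ord <- with_seed(child_seed(seed, paste0("lin", ep)), sample.int(n))
    ep_loss <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      Z <- Xs[idx, , drop = FALSE] %*% W
      Z <- sweep(Z, 2L, b, `+`)
      P <- fgr_softmax(Z, rows = TRUE)
      ep_loss <- ep_loss - sum(Tm[idx, , drop = FALSE] * log(pmax(P, 1e-12)))
      dZ <- (P - Tm[idx, , drop = FALSE]) / length(idx)
      gW <- crossprod(Xs[idx, , drop = FALSE], dZ)
      gb <- colSums(dZ)
      vW <- momentum * vW - lr_t * gW; vb <- momentum * vb - lr_t * gb
      W <- W + vW; b <- b + vb
    }
    acc <- NA_real_
    if (!is.null(X_val)) {
      Zv <- sweep(sweep(X_val, 2L, mu), 2L, sdv, `/`) %*% W
      Zv <- sweep(Zv, 2L, b, `+`)
      acc <- mean(max.col(Zv) - 1L == y_val)
      if (isTRUE(acc >= best$acc)) best <- list(acc = acc, W = W, b = b)
    }
    log_rows[[ep]] <- data.frame(epoch = ep, lr = lr_t, loss = ep_loss / n,
                                 val_acc = acc)
  }
  list(W = W, b = b, mu = mu, sd = sdv, log = do.call(rbind, log_rows),
       best_acc = if (is.null(X_val)) NA_real_ else best$acc)
}
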