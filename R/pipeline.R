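# Training / evaluation / ablation pipelines tying the modules together.

ensure_dir <- function(d) {
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

write_metrics <- function(metrics, out_dir, name = "metrics.json") {
  jsonlite::write_json(metrics, file.path(out_dir, name),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Generate the synthetic datasets named in a configuration
#'
#' Writes a classification tree (train/test crops of `n_classes` species
#' at the configured similarity) and, for detection tasks, a scene tree
#' with YOLO labels, under `cfg$data_dir`.
#'
#' @param cfg an [fgr_config()].
#' @param what `"classification"`, `"detection"` or `"both"`.
#' @return list of manifests, invisibly.
#' @export
fgr_generate <- function(cfg, what = "both") {
  lib <- fgr_make_species_library(cfg$n_classes, cfg$similarity,
                                  child_seed(cfg$seed, "library"))
  out <- list()
  if (what %in% c("classification", "both")) {
    n <- cfg$n_classes * (cfg$n_train_per_class + cfg$n_val_per_class)
    frac_train <- cfg$n_train_per_class /
      (cfg$n_train_per_class + cfg$n_val_per_class)
    out$classification <- fgr_write_dataset(
      file.path(cfg$data_dir, "cls"), lib, n,
      split_ratios = c(train = frac_train, test = 1 - frac_train),
      type = "classification", size = cfg$image_size,
      seed = child_seed(cfg$seed, "cls"))
  }
  if (what %in% c("detection", "both")) {
    sc <- fgr_scene_spec(image_size = cfg$scene_size, n_instances = 4L,
                         occlusion_prob = 0.35,
                         scale_range = c(24L, min(48L, cfg$scene_size %/% 2L)))
    out$detection <- fgr_write_dataset(
      file.path(cfg$data_dir, "det"), lib, cfg$n_scenes,
      split_ratios = c(train = 0.7, test = 0.3),
      type = "detection", scene = sc,
      seed = child_seed(cfg$seed, "det"))
  }
  invisible(out)
}

# Cache features for a list of images under a model.
extract_all <- function(model, images) lapply(images, function(im) {
  fgr_extract_features(model, im)
})

#' Train the fine-grained classifier
#'
#' Loads the classification tree under `cfg$data_dir/cls`, builds the
#' model from the seed, extracts frozen-backbone features once, and trains
#' the graph-embedding stack with label-smoothed cross-entropy, SGD and
#' cosine annealing. Saves the best checkpoint and a JSON training log
#' under `cfg$out_dir`.
#'
#' @param cfg an [fgr_config()].
#' @param verbose print per-epoch progress.
#' @return list with the trained `model`, `log`, `best_acc` and the
#'   checkpoint path.
#' @export
fgr_train_classifier <- function(cfg, verbose = FALSE) {
  dd <- file.path(cfg$data_dir, "cls")
  if (!dir.exists(dd)) stop("classification dataset not found at ", dd,
                            " (run fgr_generate first)")
  tr <- load_classification_split(dd, "train")
  te <- load_classification_split(dd, "test")
  K <- length(tr$class_names)
  model <- fgr_model(K, fgr_default_stages(cfg$stage_widths, cfg$n_blocks,
                                           cfg$shuffle_groups),
                     Dh = cfg$Dh, max_nodes = cfg$max_nodes,
                     seed = child_seed(cfg$seed, "model"))
  feats_tr <- extract_all(model, tr$images)
  feats_te <- extract_all(model, te$images)
  fit <- fgr_train_gfe(model$gfe, feats_tr, tr$labels, K,
                       feats_val = feats_te, y_val = te$labels,
                       epochs = cfg$epochs, batch_size = cfg$batch_size,
                       lr = cfg$lr, momentum = cfg$momentum,
                       period = cfg$cosine_period, eps = cfg$eps,
                       weight_decay = cfg$weight_decay,
                       seed = child_seed(cfg$seed, "sgd"),
                       verbose = verbose)
  model$gfe <- fit$best_gfe
  model$bank_stats <- fit$stats
  ensure_dir(cfg$out_dir)
  ckpt <- file.path(cfg$out_dir, "classifier.rds")
  fgr_save_checkpoint(model, ckpt)
  write_metrics(list(task = "classify", best_val_acc = fit$best_acc,
                     epochs = cfg$epochs,
                     final_loss = fit$log$loss[nrow(fit$log)]),
                cfg$out_dir)
  utils::write.csv(fit$log, file.path(cfg$out_dir, "train_log.csv"),
                   row.names = FALSE)
  invisible(list(model = model, log = fit$log, best_acc = fit$best_acc,
                 checkpoint = ckpt, class_names = tr$class_names))
}

#' Evaluate a trained classifier
#'
#' Runs inference over a split, reports accuracy and the confusion
#' matrix, and writes `metrics.json` plus a confusion-matrix heat map.
#'
#' @param model trained model (or checkpoint path).
#' @param cfg configuration (supplies data/out dirs).
#' @param split dataset split name.
#' @return list with `acc`, `confusion`, `pred`.
#' @export
fgr_evaluate_classifier <- function(model, cfg, split = "test") {
  if (is.character(model)) model <- fgr_load_checkpoint(model)
  dd <- file.path(cfg$data_dir, "cls")
  ds <- load_classification_split(dd, split)
  if (length(ds$class_names) != model$n_classes) {
    stop("checkpoint has ", model$n_classes, " classes but dataset has ",
         length(ds$class_names))
  }
  pred <- vapply(ds$images, function(im) {
    which.max(fgr_predict(model, im)) - 1L
  }, 0L)
  acc <- mean(pred == ds$labels)
  cm <- fgr_confusion_matrix(pred, ds$labels, model$n_classes)
  ensure_dir(cfg$out_dir)
  write_metrics(list(task = "evaluate", split = split, acc = acc),
                cfg$out_dir, "eval_metrics.json")
  fgr_render_confusion(cm, file.path(cfg$out_dir, "confusion.ppm"))
  list(acc = acc, confusion = cm, pred = pred)
}

#' Ablation harness
#'
#' Trains four variants under one seed and budget on the same cached
#' backbone features — backbone+GAP, +CTA (attention-pooled features,
#' linear head), +GFE (graph embedding over uniform-grid nodes), and the
#' full CTA+GFE stack — and tabulates their validation accuracies.
#'
#' @param cfg an [fgr_config()].
#' @return data.frame with columns `variant` and `val_acc` (4 rows).
#' @export
fgr_ablate <- function(cfg) {
  dd <- file.path(cfg$data_dir, "cls")
  tr <- load_classification_split(dd, "train")
  te <- load_classification_split(dd, "test")
  K <- length(tr$class_names)
  model <- fgr_model(K, fgr_default_stages(cfg$stage_widths, cfg$n_blocks,
                                           cfg$shuffle_groups),
                     Dh = cfg$Dh, max_nodes = cfg$max_nodes,
                     seed = child_seed(cfg$seed, "model"))
  feats_tr <- extract_all(model, tr$images)
  feats_te <- extract_all(model, te$images)
  sgd_seed <- child_seed(cfg$seed, "sgd")
  args <- list(epochs = cfg$epochs, batch_size = cfg$batch_size,
               lr = cfg$lr, momentum = cfg$momentum,
               period = cfg$cosine_period, eps = cfg$eps, seed = sgd_seed)
  gfe_args <- c(args, list(weight_decay = cfg$weight_decay))
  stack_feats <- function(slot) {
    list(tr = t(vapply(feats_tr, `[[`, numeric(length(feats_tr[[1]][[slot]])),
                       slot)),
         te = t(vapply(feats_te, `[[`, numeric(length(feats_te[[1]][[slot]])),
                       slot)))
  }
  gapf <- stack_feats("gap")
  fit_gap <- do.call(fgr_train_linear,
                     c(list(X = gapf$tr, y = tr$labels, K = K,
                            X_val = gapf$te, y_val = te$labels), args))
  ctaf <- stack_feats("cta")
  fit_cta <- do.call(fgr_train_linear,
                     c(list(X = ctaf$tr, y = tr$labels, K = K,
                            X_val = ctaf$te, y_val = te$labels), args))
  fit_gfe <- do.call(fgr_train_gfe,
                     c(list(gfe = model$gfe, feats_train = feats_tr,
                            y_train = tr$labels, K = K,
                            feats_val = feats_te, y_val = te$labels,
                            slot = "M_uniform"), gfe_args))
  fit_full <- do.call(fgr_train_gfe,
                      c(list(gfe = model$gfe, feats_train = feats_tr,
                             y_train = tr$labels, K = K,
                             feats_val = feats_te, y_val = te$labels,
                             slot = "M"), gfe_args))
  tab <- data.frame(
    variant = c("backbone_gap", "cta", "gfe", "cta_gfe"),
    val_acc = c(fit_gap$best_acc, fit_cta$best_acc,
                fit_gfe$best_acc, fit_full$best_acc))
  ensure_dir(cfg$out_dir)
  utils::write.csv(tab, file.path(cfg$out_dir, "ablation.csv"),
                   row.names = FALSE)
  tab
}

# ---- detector ----------------------------------------------------------

anchors_from_cfg <- function(cfg) {
  matrix(cfg$anchors, ncol = 2L, byrow = TRUE)
}

# Assign each truth box to (cell row, cell col, anchor): the cell holding
# its center and the anchor with the best wh-IoU.
assign_targets <- function(truth, anchors, stride, grid) {
  if (nrow(truth) == 0L) return(NULL)
  out <- list()
  for (i in seq_len(nrow(truth))) {
    b <- truth[i, ]
    cx <- (b$x1 + b$x2) / 2; cy <- (b$y1 + b$y2) / 2
    col_ <- min(grid[2L] - 1L, max(0L, floor(cx / stride)))
    row_ <- min(grid[1L] - 1L, max(0L, floor(cy / stride)))
    w <- b$x2 - b$x1; h <- b$y2 - b$y1
    wh_iou <- vapply(seq_len(nrow(anchors)), function(a) {
      iw <- min(w, anchors[a, 1L]); ih <- min(h, anchors[a, 2L])
      (iw * ih) / (w * h + anchors[a, 1L] * anchors[a, 2L] - iw * ih)
    }, 0)
    out[[i]] <- list(row = row_ + 1L, col = col_ + 1L,
                     anchor = which.max(wh_iou),
                     box = c(b$x1, b$y1, b$x2, b$y2),
                     class_id = b$class_id)
  }
  out
}

det_head_raw <- function(Fmat, W, b) sweep(Fmat %*% W, 2L, b, `+`)

# Loss and gradient w.r.t. the raw activation grid for one scene.
# Raw is (cells x A*per); analytic gradients for objectness (BCE) and
# class (softmax CE); central finite differences for the CIoU box term.
det_loss_grad <- function(raw, targets, head, stride, grid, K) {
  nA <- nrow(head$anchors); per <- 5L + K
  ncell <- nrow(raw)
  obj_t <- matrix(0, ncell, nA)
  dRaw <- raw * 0
  l_obj <- 0; l_cls <- 0; l_box <- 0
  assigned <- list()
  if (!is.null(targets)) for (tg in targets) {
    ci <- (tg$col - 1L) * grid[1L] + tg$row      # cell index, row fastest
    obj_t[ci, tg$anchor] <- 1
    assigned[[length(assigned) + 1L]] <- c(ci, tg$anchor)
  }
  # balanced objectness BCE: positives are outnumbered ~100:1 by empty
  # cells, so positive and negative terms are averaged separately and
  # added — otherwise positive confidence saturates far below 1
  n_pos <- max(1, sum(obj_t))
  n_neg <- max(1, ncell * nA - sum(obj_t))
  for (a in seq_len(nA)) {
    off <- (a - 1L) * per
    o <- raw[, off + 5L]
    p <- fgr_sigmoid(o)
    wts <- ifelse(obj_t[, a] > 0, 1 / (2 * n_pos), 1 / (2 * n_neg))
    l_obj <- l_obj - sum(wts * (obj_t[, a] * log(pmax(p, 1e-12)) +
                                  (1 - obj_t[, a]) * log(pmax(1 - p, 1e-12))))
    dRaw[, off + 5L] <- wts * (p - obj_t[, a])
  }
  if (!is.null(targets)) {
    nt <- length(targets)
    for (tg in targets) {
      ci <- (tg$col - 1L) * grid[1L] + tg$row
      off <- (tg$anchor - 1L) * per
      z <- raw[ci, off + 5L + seq_len(K)]
      p <- fgr_softmax(z)
      tvec <- rep(0, K); tvec[tg$class_id + 1L] <- 1
      l_cls <- l_cls - log(pmax(p[tg$class_id + 1L], 1e-12))
      dRaw[ci, off + 5L + seq_len(K)] <-
        dRaw[ci, off + 5L + seq_len(K)] + (p - tvec) / nt
      # box: CIoU via central differences on the 4 pre-decode activations
      tx <- raw[ci, off + 1:4]
      cell_rc <- c(tg$row - 1L, tg$col - 1L)
      anc <- head$anchors[tg$anchor, ]
      fbox <- function(tv) {
        fgr_ciou_loss(stats::setNames(as.list(decode_box(tv, cell_rc, anc,
                                                         stride)),
                                      c("x1", "y1", "x2", "y2")),
                      stats::setNames(as.list(tg$box),
                                      c("x1", "y1", "x2", "y2")))
      }
      l_box <- l_box + fbox(tx)
      h <- 1e-4
      gb <- vapply(1:4, function(d) {
        e <- rep(0, 4); e[d] <- h
        (fbox(tx + e) - fbox(tx - e)) / (2 * h)
      }, 0)
      dRaw[ci, off + 1:4] <- dRaw[ci, off + 1:4] + gb / nt
    }
    l_cls <- l_cls / nt; l_box <- l_box / nt
  }
  list(dRaw = dRaw, obj = l_obj, cls = l_cls, box = l_box)
}

#' Train the toy grid-anchor detector
#'
#' The frozen backbone's stage-3 feature map feeds a trainable 1x1
#' detection head optimized with objectness BCE + class cross-entropy +
#' CIoU box loss (components logged separately each epoch).
#'
#' @param cfg an [fgr_config()].
#' @param verbose print per-epoch losses.
#' @return list with `detector` (backbone + head + geometry), `log`,
#'   checkpoint path.
#' @export
fgr_train_detector <- function(cfg, verbose = FALSE) {
  dd <- file.path(cfg$data_dir, "det")
  if (!dir.exists(dd)) stop("detection dataset not found at ", dd)
  items <- load_detection_split(dd, "train")
  K <- cfg$n_classes
  model <- fgr_model(K, fgr_default_stages(cfg$stage_widths, cfg$n_blocks,
                                           cfg$shuffle_groups),
                     seed = child_seed(cfg$seed, "model"))
  anchors <- anchors_from_cfg(cfg)
  head <- fgr_detection_head_init(cfg$stage_widths[3L], anchors, K,
                                  seed = child_seed(cfg$seed, "head"))
  S <- dim(items[[1L]]$image)[1L]
  stride <- 2L^3L
  grid <- c(S %/% stride, S %/% stride)
  feats <- lapply(items, function(it) {
    st <- fgr_backbone_forward(it$image, model$backbone, resize = TRUE)
    as_position_matrix(unclass(st$stage3))
  })
  # scale features to unit-ish row norm so one SGD step moves a cell's
  # activations by O(lr * gradient); the scale is folded back into the
  # stored head weights so inference uses raw features
  fscale <- sqrt(mean(unlist(lapply(feats, function(f) rowSums(f^2)))))
  feats <- lapply(feats, function(f) f / fscale)
  targets <- lapply(items, function(it) {
    assign_targets(it$truth, anchors, stride, grid)
  })
  W <- matrix(head$W, dim(head$W)[3L], dim(head$W)[4L])
  b <- head$b
  vW <- W * 0; vb <- b * 0
  n <- length(items)
  log_rows <- list()
  # per-column learning rates: the objectness/class BCE gradients are
  # averaged over every cell while the CIoU gradients touch only the few
  # assigned cells and are much steeper, so the box columns get their own
  # (much smaller) rate. Column groups are disjoint, so this is exact.
  per <- 5L + K
  nA <- nrow(anchors)
  box_cols <- as.vector(vapply(seq_len(nA), function(a) {
    (a - 1L) * per + 1:4
  }, integer(4)))
  lr_col <- rep(1, ncol(W)); lr_col[box_cols] <- cfg$det_box_lr / cfg$det_lr
  for (ep in seq_len(cfg$det_epochs)) {
    lr_t <- cosine_lr(ep, cfg$det_lr, cfg$cosine_period)
    comp <- c(obj = 0, cls = 0, box = 0)
    # full-batch accumulation: per-scene updates with momentum proved
    # unstable for the steep CIoU gradients near poor overlaps
    gW <- W * 0; gb <- b * 0
    for (i in seq_len(n)) {
      raw <- det_head_raw(feats[[i]], W, b)
      lg <- det_loss_grad(raw, targets[[i]], head, stride, grid, K)
      if (!all(is.finite(c(lg$obj, lg$cls, lg$box)))) {
        stop("detector training diverged at epoch ", ep)
      }
      comp <- comp + c(lg$obj, lg$cls, lg$box)
      gW <- gW + crossprod(feats[[i]], lg$dRaw)
      gb <- gb + colSums(lg$dRaw)
    }
    vW <- cfg$momentum * vW - lr_t * sweep(gW, 2L, lr_col, `*`) / n
    vb <- cfg$momentum * vb - lr_t * (gb * lr_col) / n
    W <- W + vW; b <- b + vb
    comp <- comp / n
    log_rows[[ep]] <- data.frame(epoch = ep, lr = lr_t, obj = comp["obj"],
                                 cls = comp["cls"], box = comp["box"])
    if (verbose) message(sprintf(
      "epoch %3d  obj %.4f  cls %.4f  box %.4f", ep, comp["obj"],
      comp["cls"], comp["box"]))
  }
  head$W <- array(W / fscale, c(1L, 1L, nrow(W), ncol(W)))
  head$b <- b
  detector <- list(model = model, head = head, stride = stride,
                   n_classes = K)
  ensure_dir(cfg$out_dir)
  ckpt <- file.path(cfg$out_dir, "detector.rds")
  fgr_save_checkpoint(detector, ckpt)
  log <- do.call(rbind, log_rows); rownames(log) <- NULL
  utils::write.csv(log, file.path(cfg$out_dir, "det_log.csv"),
                   row.names = FALSE)
  invisible(list(detector = detector, log = log, checkpoint = ckpt))
}

#' Run the detector on one image
#'
#' Backbone stage-3 features -> head decode -> confidence filter -> NMS.
#'
#' @param detector from [fgr_train_detector()].
#' @param image scene array.
#' @param nms `"soft"`, `"hard"` or `"none"`.
#' @param Nt,score_floor NMS parameters.
#' @param conf_thresh pre-NMS confidence filter.
#' @return [fgr_detections()] table.
#' @export
fgr_detect <- function(detector, image, nms = "soft", Nt = 0.5,
                       score_floor = 0.001, conf_thresh = 0.2) {
  st <- fgr_backbone_forward(image, detector$model$backbone, resize = TRUE)
  dets <- fgr_detection_head(st$stage3, detector$head, detector$stride)
  dets <- dets[dets$score >= conf_thresh, , drop = FALSE]
  class(dets) <- c("fgr_detections", "data.frame")
  if (nrow(dets) == 0L || nms == "none") return(dets)
  switch(nms,
         soft = fgr_soft_nms(dets, Nt, score_floor),
         hard = fgr_hard_nms(dets, Nt, score_floor),
         stop("unknown nms mode ", nms))
}

#' Evaluate a detector over a scene split
#'
#' Decode -> NMS -> greedy matching; reports precision, recall and
#' macro AP at `cfg$iou_thresh`, written to `eval_det.json`.
#'
#' @param detector detector object or checkpoint path.
#' @param cfg an [fgr_config()].
#' @param split split name.
#' @param nms NMS variant (default from cfg).
#' @return list with `P`, `R`, `AP`, counts and per-scene detections.
#' @export
fgr_evaluate_detector <- function(detector, cfg, split = "test",
                                  nms = NULL) {
  if (is.character(detector)) detector <- fgr_load_checkpoint(detector)
  if (is.null(nms)) nms <- cfg$nms
  items <- load_detection_split(file.path(cfg$data_dir, "det"), split)
  all_pred <- list(); all_truth <- list()
  TP <- 0L; FP <- 0L; FN <- 0L
  for (i in seq_along(items)) {
    d <- fgr_detect(detector, items[[i]]$image, nms = nms, Nt = cfg$Nt,
                    score_floor = cfg$score_floor,
                    conf_thresh = cfg$conf_thresh)
    pr <- fgr_detection_pr(d, items[[i]]$truth, cfg$iou_thresh)
    TP <- TP + pr$TP; FP <- FP + pr$FP; FN <- FN + pr$FN
    d$scene <- rep(i, nrow(d))
    items[[i]]$truth$scene <- rep(i, nrow(items[[i]]$truth))
    all_pred[[i]] <- d; all_truth[[i]] <- items[[i]]$truth
  }
  # dataset AP: offset boxes per scene so cross-scene boxes never overlap
  offset_boxes <- function(lst) {
    do.call(rbind, lapply(lst, function(d) {
      if (!nrow(d)) return(d)
      off <- d$scene * 10000
      d$x1 <- d$x1 + off; d$x2 <- d$x2 + off
      d
    }))
  }
  preds <- offset_boxes(all_pred); truths <- offset_boxes(all_truth)
  ap <- if (nrow(truths)) {
    fgr_average_precision(preds, truths, cfg$iou_thresh)
  } else NA_real_
  prr <- fgr_precision_recall(fgr_confusion_counts(TP, 0L, FP, FN))
  res <- list(P = unname(prr["P"]), R = unname(prr["R"]), AP = ap,
              TP = TP, FP = FP, FN = FN, nms = nms)
  ensure_dir(cfg$out_dir)
  write_metrics(res, cfg$out_dir, sprintf("eval_det_%s.json", nms))
  res$detections <- all_pred
  res
}
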