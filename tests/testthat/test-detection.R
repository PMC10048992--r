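box <- function(x1, y1, x2, y2) list(x1 = x1, y1 = y1, x2 = x2, y2 = y2)

test_that("iou closed forms, symmetry and range", {
  a <- box(0, 0, 10, 10)
  expect_equal(fgr_iou(a, a), 1)
  expect_equal(fgr_iou(a, box(20, 20, 30, 30)), 0)      # disjoint, clamped
  expect_equal(fgr_iou(a, box(0, 0, 10, 5)), 0.5)       # 50/(100+50-50)
  set.seed(71)
  for (k in 1:25) {
    b1 <- box(runif(1, 0, 5), runif(1, 0, 5), runif(1, 6, 12), runif(1, 6, 12))
    b2 <- box(runif(1, 0, 5), runif(1, 0, 5), runif(1, 6, 12), runif(1, 6, 12))
    v <- fgr_iou(b1, b2)
    expect_equal(v, fgr_iou(b2, b1))
    expect_true(v >= 0 && v <= 1)
    expect_equal(v, iou_ref(b1, b2))
  }
  expect_error(fgr_iou(box(0, 0, 0, 5), a), "degenerate")
  expect_error(fgr_box(1, 1, 1, 3), "degenerate")
})

test_that("hard NMS keeps singletons and disjoint boxes, matches reference", {
  one <- fgr_detections(data.frame(x1 = 0, y1 = 0, x2 = 5, y2 = 5),
                        score = 0.7, class_id = 0L)
  expect_equal(nrow(fgr_hard_nms(one, 0.5)), 1L)
  expect_equal(fgr_hard_nms(one, 0.5)$score, 0.7)
  two <- fgr_detections(data.frame(x1 = c(0, 50), y1 = c(0, 50),
                                   x2 = c(5, 60), y2 = c(5, 60)),
                        score = c(0.9, 0.8), class_id = c(0L, 0L))
  expect_equal(nrow(fgr_hard_nms(two, 0.3)), 2L)
  expect_equal(nrow(fgr_hard_nms(empty_boxes <- two[0, ], 0.3)), 0L)
  set.seed(72)
  for (k in 1:25) {
    d <- random_dets(sample(2:50, 1))
    got <- fgr_hard_nms(d, 0.45)
    ref <- hard_nms_ref(as.data.frame(d), 0.45)
    expect_equal(got$score, ref$score)
    expect_equal(got$x1, ref$x1)
    # kept scores are a subset of input scores
    expect_true(all(got$score %in% d$score))
  }
})

test_that("soft NMS decays per the linear rule and matches the reference", {
  # two boxes, IoU 0.5, Nt 0.3: second rescored to 0.8 * (1 - 0.5) = 0.4
  d <- fgr_detections(data.frame(x1 = c(0, 0), y1 = c(0, 0),
                                 x2 = c(10, 10), y2 = c(10, 5)),
                      score = c(0.9, 0.8), class_id = c(0L, 0L))
  out <- fgr_soft_nms(d, Nt = 0.3, score_floor = 0.001)
  expect_equal(sort(out$score), c(0.4, 0.9))
  # all pairwise IoU < Nt: identity on scores
  far <- fgr_detections(data.frame(x1 = c(0, 40, 80), y1 = c(0, 40, 80),
                                   x2 = c(10, 50, 90), y2 = c(10, 50, 90)),
                        score = c(0.5, 0.9, 0.7), class_id = rep(0L, 3))
  expect_equal(sort(fgr_soft_nms(far, 0.5)$score), sort(far$score))
  set.seed(73)
  for (k in 1:25) {
    d <- random_dets(sample(2:50, 1))
    got <- fgr_soft_nms(d, 0.4, 0.02)
    ref <- soft_nms_ref(as.data.frame(d), 0.4, 0.02)
    expect_equal(got$score, ref$score)
    expect_equal(got$x1, ref$x1)
    # never increases a score
    expect_true(all(got$score <= max(d$score) + 1e-12))
  }
})

test_that("soft NMS with zeroed decay reproduces the hard-NMS kept set", {
  set.seed(74)
  for (k in 1:10) {
    d <- random_dets(sample(3:40, 1))
    hard <- fgr_hard_nms(d, 0.45)
    zeroed <- soft_nms_ref(as.data.frame(d), 0.45, 0.02,
                           decay = function(ov) 0)
    expect_equal(sort(zeroed$x1), sort(hard$x1))
    expect_equal(sort(zeroed$score), sort(hard$score))
  }
})

test_that("soft NMS with Nt near 1 is the identity on scores", {
  set.seed(75)
  d <- random_dets(30)
  out <- fgr_soft_nms(d, Nt = 0.999999, score_floor = 0)
  expect_equal(sort(out$score), sort(d$score))
})

test_that("both NMS variants ignore input ordering", {
  set.seed(76)
  d <- random_dets(25)
  perm <- sample.int(nrow(d))
  dp <- d[perm, ]; class(dp) <- class(d)
  for (f in list(function(x) fgr_hard_nms(x, 0.5),
                 function(x) fgr_soft_nms(x, 0.5, 0.01))) {
    a <- f(d); b <- f(dp)
    expect_equal(a$score, b$score)
    expect_equal(a$x1, b$x1)
  }
})

test_that("detection head decodes the documented zero-activation state", {
  head <- fgr_detection_head_init(8L, rbind(c(16, 12), c(30, 24)), 4L,
                                  seed = 3L)
  head$W[] <- 0; head$b[] <- 0
  feat <- fgr_feature_map(array(rnorm(3 * 3 * 8), c(3, 3, 8)), 3L)
  dets <- fgr_detection_head(feat, head, stride = 8)
  expect_equal(nrow(dets), 3 * 3 * 2)               # S*S*A detections
  expect_equal(unique(dets$score), 0.5 * (1 / 4))   # sigmoid(0) * 1/K
  cells <- attr(dets, "cells")
  cx <- (dets$x1 + dets$x2) / 2
  expect_equal(cx, (cells$col - 1 + 0.5) * 8)       # centered on cells
  w <- dets$x2 - dets$x1
  expect_equal(sort(unique(round(w, 9))), c(16, 30)) # anchor sizes
})

test_that("box encode/decode round-trips", {
  set.seed(78)
  anc <- c(20, 15)
  for (k in 1:20) {
    cell <- c(sample(0:5, 1), sample(0:5, 1))
    stride <- 8
    cx <- (cell[2] + runif(1, 0.05, 0.95)) * stride
    cy <- (cell[1] + runif(1, 0.05, 0.95)) * stride
    w <- runif(1, 5, 60); h <- runif(1, 5, 60)
    b <- c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
    t_ <- fgrec:::encode_box(b, cell, anc, stride)
    b2 <- fgrec:::decode_box(t_, cell, anc, stride)
    expect_equal(b2, b, tolerance = 1e-6)
  }
})

test_that("YOLO label files round-trip with scores", {
  d <- data.frame(class_id = c(0L, 2L), x1 = c(10, 40), y1 = c(20, 8),
                  x2 = c(30, 90), y2 = c(60, 58), score = c(0.9, 0.25))
  f <- tempfile(fileext = ".txt")
  fgr_write_yolo(d, f, image_size = c(100, 80))
  lines <- readLines(f)
  expect_length(lines, 2L)
  fields <- strsplit(lines, " ")[[1]]
  expect_length(fields, 6L)
  vals <- as.numeric(fields[-1])
  expect_true(all(vals >= 0 & vals <= 1))
  back <- fgr_read_yolo(f, image_size = c(100, 80))
  expect_equal(back$x1, d$x1, tolerance = 1e-3)
  expect_equal(back$y2, d$y2, tolerance = 1e-3)
  expect_equal(back$class_id, d$class_id)
  unlink(f)
  expect_equal(nrow(fgr_read_yolo(f, c(10, 10))), 0L)
})
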