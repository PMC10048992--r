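test_that("species library: determinism, structure, similarity contraction", {
  expect_error(fgr_make_species_library(1L, 0.5, 1L), "2 classes")
  a <- fgr_make_species_library(8, 0.9, seed = 5L)
  b <- fgr_make_species_library(8, 0.9, seed = 5L)
  expect_identical(a, b)
  expect_length(a, 8L)
  expect_equal(vapply(a, `[[`, 0L, "class_id"), 0:7)
  # discrete part traits cover distinct combinations
  expect_equal(vapply(a, `[[`, 0L, "wing_stripe_count"), rep(0:3, 2))
  expect_equal(vapply(a, `[[`, TRUE, "eye_ring"), rep(c(FALSE, TRUE), each = 4))
  # continuous part-parameter spread contracts as similarity -> 1
  d_hi <- fgr_species_distance(fgr_make_species_library(8, 0.9, seed = 5L))
  d_lo <- fgr_species_distance(fgr_make_species_library(8, 0.1, seed = 5L))
  expect_lt(d_hi, d_lo)
  for (s in a) {
    expect_true(all(s$body_axes > 0))
    expect_true(s$body_hue >= 0 && s$body_hue < 1)
    expect_gte(s$wing_stripe_count, 0L)
  }
})

test_that("render_crop: determinism, centering, valid range", {
  lib <- fgr_make_species_library(4, 0.5, seed = 2L)
  expect_error(fgr_render_crop(lib[[1]], 16L), ">= 32")
  c1 <- fgr_render_crop(lib[[2]], 64L, augment = FALSE, seed = 9L)
  c2 <- fgr_render_crop(lib[[2]], 64L, augment = FALSE, seed = 9L)
  expect_identical(c1, c2)
  expect_true(all(c1 >= 0 & c1 <= 1))
  # augmentation changes pixels but stays deterministic per seed
  a1 <- fgr_render_crop(lib[[2]], 64L, augment = TRUE, seed = 9L)
  a2 <- fgr_render_crop(lib[[2]], 64L, augment = TRUE, seed = 9L)
  expect_identical(a1, a2)
  expect_false(identical(a1, c1))
  # without augmentation the sprite is centered: mask extent symmetric
  # within the construction margin
  sp <- fgrec:::render_bird_sprite(lib[[2]], 64L)
  rows <- range(which(rowSums(sp$mask) > 0))
  expect_lt(abs(mean(rows) - 32.5), 8)   # documented margin
})

test_that("the beak is a small discriminative part (< 10% of pixels)", {
  lib <- fgr_make_species_library(4, 0.5, seed = 3L)
  spec <- lib[[2]]
  tiny <- spec; tiny$beak_size <- 1e-6
  s_full <- fgrec:::render_bird_sprite(spec, 64L)
  s_tiny <- fgrec:::render_bird_sprite(tiny, 64L)
  beak_px <- sum(s_full$mask != s_tiny$mask |
                   apply(abs(s_full$rgb - s_tiny$rgb) > 1e-9, c(1, 2), any))
  expect_gt(beak_px, 0)
  expect_lt(beak_px / (64 * 64), 0.10)
})

test_that("render_scene: bounds, occlusion bookkeeping, determinism", {
  lib <- fgr_make_species_library(6, 0.7, seed = 4L)
  empty <- fgr_render_scene(lib, fgr_scene_spec(n_instances = 0L, seed = 8L))
  expect_equal(nrow(empty$truth), 0L)
  expect_equal(dim(empty$image), c(128, 128, 3))
  sc <- fgr_scene_spec(image_size = 128L, n_instances = 5L,
                       occlusion_prob = 0.5, seed = 31L)
  r1 <- fgr_render_scene(lib, sc)
  r2 <- fgr_render_scene(lib, sc)
  expect_identical(r1, r2)
  expect_equal(nrow(r1$truth), 5L)
  expect_true(all(r1$truth$x1 >= 0 & r1$truth$y1 >= 0 &
                    r1$truth$x2 <= 128 & r1$truth$y2 <= 128))
  expect_true(all(r1$truth$x2 > r1$truth$x1 & r1$truth$y2 > r1$truth$y1))
  expect_true(all(r1$truth$class_id %in% 0:5))
  expect_true(all(r1$image >= 0 & r1$image <= 1))
})

test_that("write_dataset: split counts, label format, byte-identical reruns", {
  lib <- fgr_make_species_library(4, 0.5, seed = 6L)
  d1 <- file.path(tempdir(), "ds_a"); d2 <- file.path(tempdir(), "ds_b")
  unlink(c(d1, d2), recursive = TRUE)
  man <- fgr_write_dataset(d1, lib, 20L, c(train = 0.7, test = 0.3),
                           type = "classification", size = 64L, seed = 11L)
  expect_equal(man$counts$train, 14L)
  expect_equal(man$counts$test, 6L)
  expect_equal(length(list.files(d1, pattern = "\\.ppm$", recursive = TRUE)),
               20L)
  # detection tree with YOLO labels
  sc <- fgr_scene_spec(n_instances = 3L)
  mdet <- fgr_write_dataset(d2, lib, 10L, c(train = 0.7, test = 0.3),
                            type = "detection", scene = sc, seed = 12L)
  expect_equal(mdet$counts$train + mdet$counts$test, 10L)
  labs <- list.files(file.path(d2, "labels"), recursive = TRUE,
                     full.names = TRUE)
  expect_gt(length(labs), 0L)
  for (lf in labs) {
    for (ln in readLines(lf)) {
      fields <- strsplit(ln, "\\s+")[[1]]
      expect_length(fields, 5L)
      v <- as.numeric(fields[-1])
      expect_true(all(v >= 0 & v <= 1))
    }
  }
  # byte-identical regeneration under the same seed
  d3 <- file.path(tempdir(), "ds_c")
  unlink(d3, recursive = TRUE)
  fgr_write_dataset(d3, lib, 10L, c(train = 0.7, test = 0.3),
                    type = "detection", scene = sc, seed = 12L)
  f2 <- sort(list.files(d2, recursive = TRUE))
  f3 <- sort(list.files(d3, recursive = TRUE))
  expect_identical(f2, f3)
  for (f in f2) {
    expect_identical(readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     readBin(file.path(d3, f), "raw", file.size(file.path(d3, f))))
  }
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("PPM images round-trip exactly at 8-bit depth", {
  set.seed(15)
  img <- array(round(runif(12 * 10 * 3) * 255) / 255, c(12, 10, 3))
  f <- tempfile(fileext = ".ppm")
  fgr_write_ppm(img, f)
  expect_equal(fgr_read_ppm(f), img, tolerance = 1e-12)
  unlink(f)
})

test_that("high-similarity crops are genuinely fine-grained: a color
           histogram centroid classifier loses to a part-aware one", {
  # nearest-centroid on 4x4x4 color histograms vs nearest-centroid on
  # flip-symmetrized part descriptors (stripe runs, dark coverage, eye
  # ring brightness, beak extent) over the same crops
  hist_feat <- function(img) {
    b <- pmin(floor(img * 4), 3)
    idx <- b[, , 1] * 16 + b[, , 2] * 4 + b[, , 3] + 1
    tabulate(idx, 64) / length(idx)
  }
  part_feat <- function(img) {
    S <- dim(img)[1]
    f1 <- function(im) {
      body <- im[round(S * 0.40):round(S * 0.78),
                 round(S * 0.18):round(S * 0.72), , drop = FALSE]
      lum <- apply(body, c(1, 2), mean)
      colprof <- colMeans(lum)
      runs <- rle(colprof < stats::quantile(colprof, 0.35))
      head_ <- im[round(S * 0.12):round(S * 0.42),
                  round(S * 0.55):round(S * 0.95), , drop = FALSE]
      hl <- apply(head_, c(1, 2), mean)
      side <- im[round(S * 0.20):round(S * 0.44),
                 round(S * 0.80):S, , drop = FALSE]
      warm <- side[, , 1] > side[, , 3] + 0.15
      beak_len <- if (any(warm)) diff(range(which(colSums(warm) > 0))) else 0
      c(sum(runs$values), mean(lum < 0.25),
        stats::quantile(colprof, 0.9) - stats::quantile(colprof, 0.1),
        mean(hl > 0.85), max(hl), mean(warm), beak_len / S)
    }
    a <- f1(img); b <- f1(img[, dim(img)[2]:1, , drop = FALSE])
    c(pmin(a, b), pmax(a, b))
  }
  nearest_centroid_acc <- function(X, y, train_idx) {
    mu <- colMeans(X[train_idx, ]); sdv <- pmax(apply(X[train_idx, ], 2, sd), 1e-8)
    Xs <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
    cent <- sapply(sort(unique(y)), function(k) {
      colMeans(Xs[intersect(train_idx, which(y == k)), , drop = FALSE])
    })
    test_idx <- setdiff(seq_along(y), train_idx)
    pred <- apply(Xs[test_idx, ], 1, function(x) {
      which.min(colSums((cent - x)^2)) - 1
    })
    mean(pred == y[test_idx])
  }
  lib <- fgr_make_species_library(8, 0.9, seed = 5L)   # similarity >= 0.8
  y <- rep(0:7, each = 30)
  imgs <- lapply(seq_along(y), function(i) {
    fgr_render_crop(lib[[y[i] + 1]], 64L, augment = TRUE, seed = 5000L + i)
  })
  train_idx <- unlist(lapply(0:7, function(k) which(y == k)[1:22]))
  acc_hist <- nearest_centroid_acc(t(sapply(imgs, hist_feat)), y, train_idx)
  acc_part <- nearest_centroid_acc(t(sapply(imgs, part_feat)), y, train_idx)
  expect_lt(acc_hist, acc_part)
})
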