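test_that("fgr_conv2d matches the loop oracle across strides and padding", {
  set.seed(11)
  for (case in list(c(5, 6, 2, 3, 1, 0), c(6, 6, 3, 4, 2, 1),
                    c(4, 7, 1, 2, 1, 1))) {
    x <- array(rnorm(case[1] * case[2] * case[3]), case[1:3])
    w <- array(rnorm(3 * 3 * case[3] * case[4]), c(3, 3, case[3], case[4]))
    b <- rnorm(case[4])
    got <- fgr_conv2d(x, w, b, stride = case[5], pad = case[6])
    expect_equal(got, conv2d_ref(x, w, b, stride = case[5], pad = case[6]),
                 tolerance = 1e-12)
  }
})

test_that("channel shuffle is the documented fixed permutation", {
  z <- array(rep(1:4, each = 4), c(2, 2, 4))
  expect_identical(fgr_channel_shuffle(z, 1L), z)          # groups = 1
  s <- fgr_channel_shuffle(z, 2L)
  expect_equal(s[1, 1, ], c(1, 3, 2, 4))                   # enumerated map
  expect_identical(fgr_channel_shuffle(s, 2L), z)          # involution C=4 g=2
  expect_error(fgr_channel_shuffle(z, 3L), "divide")
})

test_that("channel shuffle is a permutation at every pixel", {
  set.seed(3)
  for (k in 1:5) {
    C <- sample(c(4L, 6L, 8L, 12L), 1)
    g <- sample(setdiff(which(C %% seq_len(C) == 0), 0), 1)
    x <- array(rnorm(3 * 4 * C), c(3, 4, C))
    y <- fgr_channel_shuffle(x, g)
    for (i in 1:3) for (j in 1:4) {
      expect_equal(sort(y[i, j, ]), sort(x[i, j, ]))
    }
  }
})

test_that("csp_stage honours the shape contract and errors", {
  set.seed(5)
  cfg <- fgr_stage_config(1L, 16L, 32L)
  x <- fgr_feature_map(array(rnorm(32 * 32 * 16), c(32, 32, 16)), 1L)
  withr::with_seed(1, out <- fgr_csp_stage(x, cfg))
  expect_equal(dim(out), c(16L, 16L, 32L))
  expect_s3_class(out, "fgr_feature_map")
  # ceil(H/2) x ceil(W/2) on odd inputs
  xo <- fgr_feature_map(array(rnorm(7 * 9 * 16), c(7, 9, 16)), 1L)
  withr::with_seed(1, oo <- fgr_csp_stage(xo, cfg))
  expect_equal(dim(oo)[1:2], c(4L, 5L))
  # channel mismatch and degenerate input
  bad <- fgr_feature_map(array(1, c(8, 8, 4)), 1L)
  expect_error(fgr_csp_stage(bad, cfg), "channels")
  tiny <- fgr_feature_map(array(1, c(1, 4, 16)), 1L)
  expect_error(fgr_csp_stage(tiny, cfg), "degenerate")
})

test_that("n_blocks = 0 reduces the base branch to the bare projection", {
  cfg0 <- fgr_stage_config(0L, 8L, 16L)
  x <- fgr_feature_map(array(rnorm(8 * 8 * 8), c(8, 8, 8)), 1L)
  withr::with_seed(2, p <- fgrec:::init_csp_stage(cfg0))
  expect_length(p$blocks, 0L)
  out <- fgr_csp_stage(x, cfg0, p)
  # both branches are 1x1 projections of the input; rebuild by hand
  base <- fgrec:::conv_block(unclass(x), p$w_base, p$b_base)
  cross <- fgrec:::conv_block(unclass(x), p$w_cross, p$b_cross)
  cat_ <- array(c(base, cross), c(8, 8, 16))
  manual <- fgrec:::conv_block(fgr_channel_shuffle(cat_, 2L),
                               p$w_down, p$b_down, stride = 2L, pad = 1L)
  expect_equal(unclass(out), manual, ignore_attr = TRUE)
})

test_that("a CSP stage has fewer parameters than a plain full-width stage", {
  cfg <- fgr_stage_config(2L, 32L, 64L)
  withr::with_seed(7, p <- fgrec:::init_csp_stage(cfg))
  csp_count <- fgr_param_count(p[setdiff(names(p), "cfg")])
  # independent count of the plain construction: project to full width,
  # run the same n bottlenecks at full width, downsample
  C <- cfg$out_channels; Cin <- cfg$in_channels; mid <- C %/% 2L
  plain <- (1 * 1 * Cin * C + C) +                       # full projection
    cfg$n_blocks * ((1 * 1 * C * mid + mid) +            # reduce
                      (3 * 3 * mid * C + C)) +           # expand
    (3 * 3 * C * C + C)                                  # downsample
  expect_lt(csp_count, plain)
})

test_that("backbone_forward exposes stages 2-4 with consistent halving", {
  bb <- fgrec:::init_backbone(fgr_default_stages(), seed = 9L)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  st <- fgr_backbone_forward(img, bb)
  expect_named(st, c("stage2", "stage3", "stage4"))
  expect_equal(dim(st$stage4)[1:2], c(4L, 4L))           # 64 / 2^4
  expect_equal(dim(st$stage2)[1:2], 2L * dim(st$stage3)[1:2])
  # determinism
  st2 <- fgr_backbone_forward(img, bb)
  expect_identical(st, st2)
  # indivisible input: explicit failure or resize per flag
  odd <- array(runif(70 * 70 * 3), c(70, 70, 3))
  expect_error(fgr_backbone_forward(odd, bb), "divisible")
  ok <- fgr_backbone_forward(odd, bb, resize = TRUE)
  expect_equal(dim(ok$stage4)[1:2], c(4L, 4L))
})

test_that("a zero image through a bias-free backbone stays zero", {
  bb <- fgrec:::init_backbone(fgr_default_stages(), seed = 1L)
  # strip every bias to make the stack linear at the origin
  bb$stages <- lapply(bb$stages, function(s) {
    s$b_base <- s$b_base * 0; s$b_cross <- s$b_cross * 0
    s$b_down <- s$b_down * 0
    s$blocks <- lapply(s$blocks, function(bl) {
      bl$b1 <- bl$b1 * 0; bl$b2 <- bl$b2 * 0; bl
    })
    s
  })
  img <- array(0, c(32, 32, 3))
  st <- fgr_backbone_forward(img, bb)
  for (s in st) expect_true(all(s == 0))
})

test_that("checkpoints round-trip parameter trees", {
  bb <- fgrec:::init_backbone(fgr_default_stages(), seed = 4L)
  f <- tempfile(fileext = ".rds")
  fgr_save_checkpoint(bb, f)
  expect_identical(fgr_load_checkpoint(f), bb)
  unlink(f)
})
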