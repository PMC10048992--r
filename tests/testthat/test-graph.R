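test_that("part pooling reduces to means and point reads, matches loops", {
  set.seed(41)
  feat <- fgr_feature_map(array(rnorm(2 * 2 * 3), c(2, 2, 3)), 2L)
  unif <- fgr_attention(array(1 / 4, c(2, 2, 2)), 2L)
  bank <- fgr_part_pooling(unif, feat)
  gavg <- apply(unclass(feat), 3, mean)
  expect_equal(bank$nodes[1, ], gavg)
  expect_equal(bank$nodes[2, ], gavg)
  # single-hot attention reads the feature vector at that pixel
  hot <- array(0, c(1, 2, 2)); hot[1, 2, 1] <- 1
  bh <- fgr_part_pooling(fgr_attention(hot, 2L), feat)
  expect_equal(bh$nodes[1, ], feat[2, 1, ])
  # random maps against explicit weighted-sum loops
  m <- matrix(runif(4), 2, 2); m <- m / sum(m)
  att <- fgr_attention(array(m, c(1, 2, 2)), 2L)
  br <- fgr_part_pooling(att, feat)
  ref <- numeric(3)
  for (c_ in 1:3) for (i in 1:2) for (j in 1:2) {
    ref[c_] <- ref[c_] + m[i, j] * feat[i, j, c_]
  }
  expect_equal(br$nodes[1, ], ref)
  expect_error(
    fgr_part_pooling(att, fgr_feature_map(array(1, c(3, 3, 2)), 2L)),
    "attention")
})

test_that("part pooling caps nodes by attention concentration", {
  set.seed(42)
  maps <- array(0, c(5, 2, 2))
  for (i in 1:5) maps[i, , ] <- fgr_softmax(rnorm(4) * i)  # sharper later
  att <- fgr_attention(maps, 3L)
  feat <- fgr_feature_map(array(rnorm(2 * 2 * 4), c(2, 2, 4)), 3L)
  bank <- fgr_part_pooling(att, feat, max_nodes = 2L)
  expect_equal(nrow(bank$nodes), 2L)
})

test_that("adjacency closed forms, symmetry and zero-norm handling", {
  same <- fgr_part_bank(matrix(rep(c(1, 2, 3), 3), 3, byrow = TRUE))
  At <- fgr_adjacency(same)
  expect_equal(At, matrix(1, 3, 3) + diag(3))
  ortho <- fgr_part_bank(diag(3))
  expect_equal(fgr_adjacency(ortho), 2 * diag(3))
  # random case vs hand-looped cosine
  set.seed(5)
  K <- matrix(rnorm(9), 3, 3)
  At2 <- fgr_adjacency(fgr_part_bank(K))
  for (i in 1:3) for (j in 1:3) {
    cs <- sum(K[i, ] * K[j, ]) /
      (sqrt(sum(K[i, ]^2)) * sqrt(sum(K[j, ]^2)))
    expect_equal(At2[i, j], cs + (i == j), tolerance = 1e-12)
  }
  expect_equal(At2, t(At2))
  expect_true(all(abs(At2 - diag(3)) <= 1 + 1e-12))
  # zero-norm node never yields NaN
  Kz <- rbind(c(1, 0), c(0, 0))
  Az <- fgr_adjacency(fgr_part_bank(Kz))
  expect_true(all(is.finite(Az)))
  expect_equal(Az[1, 2], 0)
  # tau transform is applied before the similarity
  tau <- matrix(c(1, 0, 0, 0), 2, 2)
  Kt <- rbind(c(1, 5), c(1, -5))
  expect_equal(fgr_adjacency(fgr_part_bank(Kt), tau)[1, 2], 1)
})

test_that("graph propagation closed forms and dense-loop oracle", {
  # single node: normalization cancels
  K1 <- matrix(c(1, -2, 3), 1, 3)
  W <- diag(3)
  G1 <- fgr_graph_propagate(fgr_part_bank(K1), matrix(2, 1, 1), W)
  expect_equal(G1, pmax(K1 %*% W / 1, 0) * 1)   # D = 2 cancels exactly
  expect_equal(G1[1, ], pmax(K1[1, ], 0))
  # A~ = 2I with identity W and nonnegative K returns K unchanged
  K2 <- matrix(runif(6), 2, 3)
  expect_equal(fgr_graph_propagate(fgr_part_bank(K2), 2 * diag(2), diag(3)),
               K2)
  # random instances <= 5 nodes, <= 4 dims against the loop oracle
  set.seed(77)
  for (rep in 1:20) {
    N <- sample(1:5, 1); D <- sample(1:4, 1); Dh <- sample(1:4, 1)
    K <- matrix(rnorm(N * D), N, D)
    At <- fgr_adjacency(fgr_part_bank(K), nonneg = TRUE)
    W <- matrix(rnorm(D * Dh), D, Dh)
    expect_equal(fgr_graph_propagate(fgr_part_bank(K), At, W),
                 propagate_ref(K, At, W), tolerance = 1e-12)
  }
  expect_error(
    fgr_graph_propagate(fgr_part_bank(diag(2)), matrix(0, 2, 2), diag(2)),
    "degree")
})

test_that("level attention: singleton, symmetry, direct evaluation", {
  G <- matrix(rnorm(12), 4, 3)
  expect_equal(fgr_level_attention(list(G))$I, 1)
  w3 <- fgr_level_attention(list(G, G, G))$I
  expect_equal(w3, rep(1 / 3, 3))
  # direct tanh + softmax evaluation with explicit parameters
  set.seed(6)
  G1 <- matrix(rnorm(6), 2, 3); G2 <- matrix(rnorm(9), 3, 3)
  G3 <- matrix(rnorm(3), 1, 3)
  pars <- list(w = c(0.5, -1, 2), b = 0.3)
  lw <- fgr_level_attention(list(G1, G2, G3), pars)
  eta <- vapply(list(G1, G2, G3), function(G) {
    mean(tanh(G %*% pars$w + pars$b))
  }, 0)
  expect_equal(lw$I, exp(eta) / sum(exp(eta)))
  expect_equal(sum(lw$I), 1)
})

test_that("level weights are permutation-equivariant", {
  set.seed(61)
  Gs <- lapply(c(2, 4, 3), function(n) matrix(rnorm(n * 3), n, 3))
  pars <- list(w = rnorm(3), b = 0.1)
  I1 <- fgr_level_attention(Gs, pars)$I
  perm <- c(3, 1, 2)
  I2 <- fgr_level_attention(Gs[perm], pars)$I
  expect_equal(I2, I1[perm])
})

test_that("fused score is a probability distribution and mixes exactly", {
  set.seed(62)
  G1 <- matrix(rnorm(8), 2, 4); G2 <- matrix(rnorm(12), 3, 4)
  heads <- list(list(W = matrix(rnorm(12), 4, 3), b = rnorm(3)),
                list(W = matrix(rnorm(12), 4, 3), b = rnorm(3)))
  # single level with unit weight equals that level's softmax
  p1 <- fgr_fused_score(list(G1), list(I = 1), heads[1])
  expect_equal(p1,
               fgr_softmax(drop(colMeans(G1) %*% heads[[1]]$W + heads[[1]]$b)))
  # hand-set weights mix the two distributions
  pa <- fgr_fused_score(list(G1), list(I = 1), heads[1])
  pb <- fgr_fused_score(list(G2), list(I = 1), heads[2])
  mix <- fgr_fused_score(list(G1, G2), list(I = c(0.3, 0.7)), heads)
  expect_equal(mix, 0.3 * pa + 0.7 * pb)
  expect_equal(sum(mix), 1)
  # arbitrary weights keep it a distribution
  for (k in 1:5) {
    I <- fgr_softmax(rnorm(2))
    p <- fgr_fused_score(list(G1, G2), list(I = I), heads)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1)
  }
  expect_error(fgr_fused_score(list(G1, G2), list(I = c(1)), heads[1]),
               "heads|levels")
})
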