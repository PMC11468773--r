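test_that("an identity policy leaves patch pairs untouched", {
  p <- toy_pairs(1)[[1]]
  out <- augment_pair(p, tomomine:::identity_policy(), seed = 5)
  expect_equal(out$P_t, p$P_t)
  expect_equal(out$P_s, p$P_s)
})

test_that("rotation-only augmentation is invertible by the inverse rotation", {
  p <- toy_pairs(1)[[1]]
  pol <- tomomine:::identity_policy()
  pol$rotate90 <- TRUE
  out <- augment_pair(p, pol, seed = 7)
  matched <- FALSE
  for (k in 0:3)
    if (isTRUE(all.equal(tomomine:::rot90_mat(out$P_t, (4 - k) %% 4), p$P_t)))
      matched <- TRUE
  expect_true(matched)
})

test_that("augmentation preserves shape and zeroes the dropout corner", {
  p <- toy_pairs(1, side = 20)[[1]]
  pol <- augment_policy()
  pol$corner_prob <- 1
  for (seed in 1:200) {
    out <- augment_pair(p, pol, seed = seed)
    expect_identical(dim(out$P_t), dim(p$P_t))
    expect_identical(dim(out$P_s), dim(p$P_s))
    expect_true(any(out$P_t == 0))
  }
  # determinism
  expect_equal(augment_pair(p, pol, seed = 3), augment_pair(p, pol, seed = 3))
})

test_that("negative cosine similarity hits its analytic anchor points", {
  v <- rnorm(128)
  expect_equal(negative_cosine(v, v), -1, tolerance = 1e-12)
  expect_equal(negative_cosine(c(1, 0), c(0, 2)), 0)
  expect_equal(negative_cosine(v, -v), 1, tolerance = 1e-12)
  expect_error(negative_cosine(numeric(128), v), "zero")
})

test_that("the symmetrized loss equals its hand-computed value", {
  set.seed(1)
  y1 <- rnorm(128); z2 <- rnorm(128); y2 <- rnorm(128); z1 <- rnorm(128)
  want <- 0.5 * negative_cosine(y1, z2) + 0.5 * negative_cosine(y2, z1)
  expect_equal(symmetrized_loss(y1, z2, y2, z1), want, tolerance = 1e-6)
  u <- rnorm(128)
  expect_equal(symmetrized_loss(u, u, 2 * u, 2 * u), -1, tolerance = 1e-12)
  expect_equal(symmetrized_loss(c(1, 0), c(0, 1), c(0, 2), c(3, 0)), 0)
})

test_that("stop-gradient: loss gradients flow to y only, and match FD", {
  set.seed(2)
  y1 <- rnorm(16); z2 <- rnorm(16); y2 <- rnorm(16); z1 <- rnorm(16)
  g <- symmetrized_loss_grads(y1, z2, y2, z1)
  expect_true(all(g$gz1 == 0))
  expect_true(all(g$gz2 == 0))
  eps <- 1e-6
  for (i in c(1, 7, 16)) {
    a <- y1; a[i] <- a[i] + eps; b <- y1; b[i] <- b[i] - eps
    expect_equal(g$gy1[i],
                 (symmetrized_loss(a, z2, y2, z1) -
                  symmetrized_loss(b, z2, y2, z1)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("training reduces the loss and is reproducible", {
  pairs <- toy_pairs(8, side = 16)
  cfg <- default_config()
  cfg$patch_side <- 16L; cfg$explore_steps <- 20L; cfg$explore_batch <- 8L
  cfg$backbone_channels <- 4L
  m <- train_exploration(pairs, cfg, tomomine:::identity_policy())
  expect_lt(mean(tail(m$loss_history, 3)), m$loss_history[1])

  m2 <- train_exploration(pairs, cfg, tomomine:::identity_policy())
  expect_identical(m$loss_history, m2$loss_history)

  cfg0 <- cfg; cfg0$explore_lr <- 0; cfg0$weight_decay <- 0
  cfg0$explore_steps <- 5L
  m0 <- train_exploration(pairs, cfg0, tomomine:::identity_policy())
  init <- tomomine:::init_exploration_model(cfg0)
  expect_equal(m0$params, init$params, tolerance = 1e-12)
  expect_error(train_exploration(list(), cfg), "empty")
})

test_that("embedding is deterministic, order-preserving and 128-dimensional", {
  pairs <- toy_pairs(6, side = 16)
  cfg <- default_config()
  cfg$patch_side <- 16L; cfg$explore_steps <- 4L; cfg$explore_batch <- 6L
  cfg$backbone_channels <- 4L
  m <- train_exploration(pairs, cfg, tomomine:::identity_policy())
  emb <- embed_dataset(m, pairs)
  expect_equal(dim(emb$z), c(6L, 128L))
  expect_equal(dim(emb$y), c(6L, 128L))
  expect_true(all(is.finite(emb$z)))
  dup <- embed_dataset(m, c(pairs, pairs[1]))
  expect_equal(dup$z[1, ], dup$z[7, ], tolerance = 1e-10)
  bad <- toy_pairs(2, side = 8)
  expect_error(embed_dataset(m, c(pairs, bad)), "mismatch")
})
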