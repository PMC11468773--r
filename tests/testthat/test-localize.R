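test_that("Gaussian targets carry the kernel profile and -1 elsewhere", {
  tab <- coord_table("t", 8, 8, 8)
  hm <- make_target_heatmap(tab, c(16, 16, 16), "globular", sigma_k = 2)
  Y <- hm$Y
  expect_equal(Y[9, 9, 9], 1)
  expect_equal(Y[11, 9, 9], exp(-1 / 2), tolerance = 1e-12)  # distance sigma
  expect_equal(Y[1, 1, 1], -1)   # far outside the truncated support

  none <- make_target_heatmap(coord_table(), c(8, 8, 8))
  expect_true(all(none$Y == -1))
})

test_that("tubular targets fill exactly the radius-3 ball", {
  tab <- coord_table("t", 8, 8, 8)
  hm <- make_target_heatmap(tab, c(16, 16, 16), "tubular", radius = 3)
  n_ball <- 0
  for (x in 0:15) for (y in 0:15) for (z in 0:15)
    if ((x - 8)^2 + (y - 8)^2 + (z - 8)^2 <= 9) n_ball <- n_ball + 1
  expect_equal(sum(hm$Y == 1), n_ball)
  expect_equal(sum(hm$Y == -1), 16^3 - n_ball)
})

test_that("overlapping annotations combine by elementwise maximum", {
  tab <- coord_table("t", c(8, 9), c(8, 8), c(8, 8))
  hm <- make_target_heatmap(tab, c(16, 16, 16), "globular", sigma_k = 2)
  expect_equal(hm$Y[9, 9, 9], 1)
  expect_equal(hm$Y[10, 9, 9], 1)
  expect_equal(hm$Y[11, 9, 9], exp(-1 / 8), tolerance = 1e-12)
})

test_that("PU risk vanishes in the perfect-classifier limit, monotonically", {
  cfg <- default_config(); cfg$pi_p <- 0.25
  Y <- array(-1, c(4, 4, 4)); Y[2, 2, 2] <- 1
  risks <- vapply(c(1e-2, 1e-3, 1e-4), function(eps) {
    yh <- array(eps, c(4, 4, 4)); yh[2, 2, 2] <- 1 - eps
    pu_focal_risk(yh, Y, cfg)
  }, numeric(1))
  expect_true(all(diff(risks) < 0))
  expect_lt(risks[3], 1e-4)
})

test_that("PU risk reduces to the unlabeled term as the prior vanishes", {
  cfg <- default_config()
  Y <- array(-1, c(3, 3, 3)); Y[1, 1, 1] <- 1
  set.seed(2)
  yh <- array(runif(27, 0.1, 0.9), c(3, 3, 3))
  cfg$pi_p <- 1e-9
  pu <- pu_focal_risk(yh, Y, cfg)
  u <- yh[Y < 0]
  r_u <- mean(-(u)^cfg$alpha * log(1 - u))
  expect_equal(pu, r_u, tolerance = 1e-6)
})

test_that("PU risk equals the per-voxel oracle on printed toy instances", {
  cfg <- default_config(); cfg$pi_p <- 0.25; cfg$pi_tp <- 0.5
  Y <- array(c(1, 0.6, -1, -1, 0.3, -1, -1, -1), c(2, 2, 2))
  yh <- array(c(0.9, 0.5, 0.2, 0.1, 0.4, 0.3, 0.25, 0.15), c(2, 2, 2))
  expect_equal(pu_focal_risk(yh, Y, cfg),
               oracle_pu_risk(yh, Y, 2, 4, 0.25, 0.5), tolerance = 1e-8)
  for (seed in 1:10) {
    set.seed(seed)
    Y <- array(-1, c(4, 4, 4))
    Y[sample(64, 3)] <- 1
    Y[sample(which(Y < 0), 6)] <- runif(6, 0.05, 0.95)
    yh <- array(runif(64, 0.02, 0.98), c(4, 4, 4))
    expect_equal(pu_focal_risk(yh, Y, cfg),
                 oracle_pu_risk(yh, Y, 2, 4, 0.25, 0.5), tolerance = 1e-8)
    expect_gte(pu_focal_risk(yh, Y, cfg), 0)   # non-negativity
  }
  expect_error(pu_focal_risk(yh, array(-1, c(4, 4, 4)), cfg), "positive")
  bad <- cfg; bad$pi_p <- 1.5
  expect_error(pu_focal_risk(yh, Y, bad), "prior")
})

test_that("supervised debiased contrastive loss matches hand evaluation", {
  t <- 1; pi_p <- 0.3
  v <- c(1, 0, 0, 0)
  Fp <- rbind(v, v, v, v)               # identical positives
  Fu <- rbind(c(0, 1, 0, 0), c(0, 0, 1, 0))  # orthogonal unlabeled
  g_sup <- max((1 - pi_p * exp(1)) / (1 - pi_p), exp(-1))
  want <- -log(exp(1) / (exp(1) + g_sup))
  expect_equal(sup_contrastive_core(Fp, Fu, pi_p, t), want, tolerance = 1e-10)
})

test_that("the debiased negative mass is floored at exp(-1/t)", {
  # positives highly similar, unlabeled anti-aligned: raw estimate < floor
  t <- 0.5
  Fp <- rbind(c(1, 0), c(1, 0))
  Fu <- rbind(c(-1, 0), c(-1, 0))
  pi_p <- 0.5
  A <- exp(1 / t); B <- exp(-1 / t)
  raw <- (B - pi_p * A) / (1 - pi_p)
  expect_lt(raw, exp(-1 / t))
  want <- -log(A / (A + exp(-1 / t)))
  expect_equal(sup_contrastive_core(Fp, Fu, pi_p, t), want, tolerance = 1e-10)
})

test_that("contrastive losses equal brute-force double-loop oracles", {
  for (seed in 1:10) {
    set.seed(seed)
    Fp <- matrix(rnorm(6 * 4), 6, 4)
    Fu <- matrix(rnorm(10 * 4), 10, 4)
    expect_equal(sup_contrastive_core(Fp, Fu, 0.3, 0.07),
                 oracle_sup_contrastive(Fp, Fu, 0.3, 0.07), tolerance = 1e-8)
    U1 <- matrix(rnorm(6 * 4), 6, 4); U2 <- matrix(rnorm(6 * 4), 6, 4)
    P1 <- matrix(rnorm(2 * 4), 2, 4); P2 <- matrix(rnorm(2 * 4), 2, 4)
    yu <- runif(6)
    expect_equal(unsup_contrastive_core(U1, U2, P1, P2, yu, 0.3, 0.07),
                 oracle_unsup_contrastive(U1, U2, P1, P2, yu, 0.3, 0.07),
                 tolerance = 1e-8)
  }
})

test_that("unsupervised pseudo-group rules follow the prediction", {
  set.seed(3)
  U1 <- matrix(rnorm(4 * 3), 4, 3); U2 <- matrix(rnorm(4 * 3), 4, 3)
  P0 <- matrix(0, 0, 3)
  # yhat = 0.5 everywhere: exactly the mean of the two pure-group losses
  mixed <- unsup_contrastive_core(U1, U2, P0, P0, rep(0.5, 4), 0.3, 1)
  lp <- unsup_contrastive_core(U1, U2, P0, P0, rep(0.95, 4), 0.3, 1)
  ln <- unsup_contrastive_core(U1, U2, P0, P0, rep(0.05, 4), 0.3, 1)
  expect_equal(mixed, 0.5 * lp + 0.5 * ln, tolerance = 1e-10)

  # single unlabeled vector with identical twin and orthogonal distractor
  U1 <- matrix(c(1, 0, 0), 1); U2 <- matrix(c(1, 0, 0), 1)
  P1 <- matrix(c(0, 1, 0), 1); P2 <- matrix(c(0, 0, 1), 1)
  t <- 1; pi_p <- 0.3; pi_n <- 0.7
  e <- exp(1); mS <- (1 + 1) / 2   # two orthogonal remaining vectors
  gp <- max((mS - pi_n * e) / pi_n, exp(-1))
  want <- -log(e / (e + gp))
  got <- unsup_contrastive_core(U1, U2, P1, P2, 0.95, pi_p, t)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("consistency loss is the mean squared difference", {
  a <- array(runif(27), c(3, 3, 3))
  expect_equal(consistency_mse(a, a), 0)
  expect_equal(consistency_mse(a, a + 0.1), 0.01, tolerance = 1e-12)
  b <- array(runif(27), c(3, 3, 3))
  expect_equal(consistency_mse(a, b), mean((a - b)^2))
  expect_error(consistency_mse(a, array(0, c(2, 2, 2))), "shape")
})

test_that("the total objective combines components with the default weights", {
  cfg <- default_config()
  expect_equal(total_loss(1.0, 0.2, 0.4, 0.3, cfg), 1.07)
  expect_equal(total_loss(0, 0, 0, 0, cfg), 0)
  abl <- cfg; abl$lambda1 <- 0; abl$lambda3 <- 0
  expect_equal(total_loss(0.8, 5, 7, 9, abl), 0.8)
})

test_that("loss gradients agree with finite differences", {
  cfg <- default_config(); cfg$pi_p <- 0.25
  set.seed(5)
  Y <- array(-1, c(3, 3, 3)); Y[c(2, 14)] <- 1; Y[c(5, 20)] <- c(0.4, 0.8)
  yh <- array(runif(27, 0.05, 0.95), c(3, 3, 3))
  g <- tomomine:::pu_focal_risk_impl(yh, Y, cfg, want_grad = TRUE)$grad
  eps <- 1e-6
  for (i in c(2, 5, 14, 20, 9)) {
    a <- yh; a[i] <- a[i] + eps; b <- yh; b[i] <- b[i] - eps
    expect_equal(g[i], (pu_focal_risk(a, Y, cfg) - pu_focal_risk(b, Y, cfg)) /
                   (2 * eps), tolerance = 1e-5)
  }
  Fp <- matrix(rnorm(4 * 3), 4, 3); Fu <- matrix(rnorm(6 * 3), 6, 3)
  s <- tomomine:::sup_contrastive_impl(Fp, Fu, 0.3, 0.5, want_grad = TRUE)
  for (i in c(1, 5, 9)) {
    a <- Fp; a[i] <- a[i] + eps; b <- Fp; b[i] <- b[i] - eps
    expect_equal(s$gFp[i],
                 (sup_contrastive_core(a, Fu, 0.3, 0.5) -
                  sup_contrastive_core(b, Fu, 0.3, 0.5)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("particle extraction keeps kernel-window maxima above threshold", {
  h <- array(0.01, c(24, 24, 12))
  for (x in 0:23) for (y in 0:23) for (z in 0:11)
    h[x + 1, y + 1, z + 1] <- h[x + 1, y + 1, z + 1] +
      0.9 * exp(-((x - 11)^2 + (y - 13)^2 + (z - 6)^2) / 8)
  out <- extract_particles(h, kernel = 5, prob_threshold = 0.5)
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$x, out$y, out$z), c(11, 13, 6))

  expect_equal(nrow(extract_particles(h * 0.4 , 5, 0.5)), 0L)

  for (seed in 1:3) {
    set.seed(seed)
    r <- array(runif(14^3), c(14, 14, 14))
    got <- extract_particles(r, 5, 0.6)
    want <- oracle_local_max(r, 5, 0.6)
    ord <- order(-want[, 4])
    expect_equal(cbind(got$x, got$y, got$z),
                 unname(want[ord, 1:3, drop = FALSE]))
  }
  expect_error(extract_particles(h, 4, 0.5), "odd")
})

test_that("extracted coordinates are pairwise non-adjacent within the kernel", {
  set.seed(9)
  r <- array(runif(20^3), c(20, 20, 20))
  out <- extract_particles(r, 7, 0.7)
  if (nrow(out) > 1) {
    dm <- as.matrix(dist(cbind(out$x, out$y, out$z), method = "maximum"))
    diag(dm) <- Inf
    expect_true(all(dm > 3))   # kernel half-width
  }
})

test_that("tubular extraction forces the kernel to 3", {
  h <- array(0.01, c(12, 12, 8))
  h[4, 4, 4] <- 0.9; h[9, 9, 5] <- 0.8
  out <- extract_particles(h, kernel = 11, prob_threshold = 0.5,
                           mode = "tubular")
  expect_equal(nrow(out), 2L)   # kernel 11 would have suppressed one
})
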