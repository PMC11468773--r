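test_that("preprocessing equalizes histograms and handles degenerate input", {
  cst <- array(2, c(8, 8, 8))
  expect_equal(unique(as.numeric(preprocess_volume(cst, 0))), 0.5)

  two <- array(0, c(8, 8, 8)); two[1:128] <- 1
  out <- preprocess_volume(two, 0)
  expect_true(all(out[two == 1] > out[two == 0][1]))

  set.seed(4)
  r <- array(rnorm(32^3), c(32, 32, 32))
  eq <- preprocess_volume(r, 0)
  cdf_dev <- max(abs(sort(as.numeric(eq)) - seq_len(length(eq)) / length(eq)))
  expect_lt(cdf_dev, 0.05)
})

test_that("DoG response peaks at blob centers and vanishes on constants", {
  v <- array(0, c(32, 32, 32))
  v <- tomomine:::splat_ball(v, c(16, 16, 16), 4, -1)  # bright blob
  resp <- dog_response(v, dog_sigma_ladder(4))
  pk <- which(resp$response == max(resp$response), arr.ind = TRUE)[1, ] - 1
  expect_lt(sqrt(sum((pk - c(16, 16, 16))^2)), 1.5)

  expect_equal(max(abs(dog_response(array(1, c(8, 8, 8)),
                                    c(1, 2))$response)), 0,
               tolerance = 1e-10)

  v2 <- tomomine:::splat_ball(v, c(6, 24, 10), 4, -1)
  resp2 <- dog_response(v2, dog_sigma_ladder(4))
  cand <- nms_3d(resp2, 5, threshold = 0.5 * max(resp2$response))
  expect_equal(nrow(cand), 2L)
  ctrs <- rbind(c(16, 16, 16), c(6, 24, 10))
  for (i in 1:2) {
    dists <- sqrt(rowSums((ctrs - matrix(unlist(cand[i, c("x", "y", "z")]),
                                         2, 3, byrow = TRUE))^2))
    expect_lt(min(dists), 1.5)
  }
  expect_error(dog_response(v, 2), "2 sigmas")
})

test_that("auto threshold is mean + 0.5 population standard deviations", {
  expect_equal(auto_threshold(array(3, c(4, 4, 4))), 3)
  r <- array(c(0, 0, 0, 4), c(4, 1, 1))
  expect_equal(auto_threshold(r), 1 + 0.5 * sqrt(3))
  set.seed(8)
  z <- array(rnorm(40^3), c(40, 40, 40))
  se <- sqrt(1 / length(z) + 0.25 / (2 * length(z)))
  expect_lt(abs(auto_threshold(z) - 0.5), 3 * se + 0.01)
})

test_that("greedy NMS resolves near and far peaks as specified", {
  r <- array(0, c(20, 20, 20))
  r[5, 5, 5] <- 2; r[8, 5, 5] <- 1        # 3 voxels apart
  out <- nms_3d(r, radius = 5, threshold = 0.5)
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$x, out$y, out$z), c(4, 4, 4))

  r[16, 5, 5] <- 1                         # 11 voxels from the high peak
  out <- nms_3d(r, radius = 5, threshold = 0.5)
  expect_equal(nrow(out), 2L)
  expect_equal(out$x, c(4, 15))            # higher peak first
})

test_that("NMS matches the brute-force greedy oracle on random volumes", {
  for (seed in 1:4) {
    set.seed(seed)
    r <- array(runif(16^3), c(16, 16, 16))
    thr <- 0.8
    for (radius in c(2, 4)) {
      got <- nms_3d(r, radius, thr, max_candidates = 1000L)
      want <- oracle_nms(r, radius, thr)
      expect_equal(nrow(got), nrow(want))
      expect_equal(cbind(got$x, got$y, got$z), unname(want[, 1:3, drop = FALSE]))
    }
  }
})

test_that("coordinate projection follows the tilt geometry exactly", {
  expect_equal(unname(project_coordinate(c(7, 3, 9), 0, c(50, 30))),
               c(7, 3), ignore_attr = TRUE)
  # rotation-center fixed point
  expect_equal(unname(project_coordinate(c(25, 4, 15), 37, c(50, 30))),
               c(25, 4), ignore_attr = TRUE)
  # hand-evaluated case: W=100, D=60, (70,10,40), theta=30
  got <- project_coordinate(c(70, 10, 40), 30, c(100, 60))
  expect_equal(unname(got[1]), 20 * cos(pi / 6) + 10 * sin(pi / 6) + 50,
               tolerance = 1e-9)
  expect_equal(unname(got[2]), 10)
})

test_that("projection mirror symmetry holds for z at the rotation center", {
  for (x in c(3, 41, 77)) {
    W <- 100; D <- 60
    p1 <- project_coordinate(c(x, 5, 30), 25, c(W, D))
    p2 <- project_coordinate(c(x, 5, 30), -25, c(W, D))
    expect_equal(unname(p1[1] + p2[1]),
                 2 * (x - 50) * cos(25 * pi / 180) + 2 * 50,
                 tolerance = 1e-9)
  }
})

test_that("patch pairs average the projected tilt patches", {
  v <- array(0, c(40, 40, 20))
  v[21, 21, 11] <- 1
  ts <- simulate_tilt_series(v, c(-10, 0, 10))
  pr <- extract_pair(v, ts, c(20, 20, 10), patch_side = 9)
  expect_equal(dim(pr$P_t), c(9, 9))
  # single tilt at 0: P_t maximum lands at the patch center
  ts0 <- simulate_tilt_series(v, 0)
  pr0 <- extract_pair(v, ts0, c(20, 20, 10), patch_side = 9)
  pk <- which(pr0$P_t == max(pr0$P_t), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(5, 5))

  # manual average over the three tilts
  acc <- matrix(0, 9, 9)
  for (i in 1:3) {
    pj <- project_coordinate(c(20, 20, 10), ts$angles[i], c(40, 20))
    acc <- acc + tomomine:::bilinear_sample(ts$images[[i]],
                                            pj[1] + (1:9) - 5,
                                            pj[2] + (1:9) - 5)
  }
  expect_equal(pr$P_t, acc / 3, tolerance = 1e-12)

  # empty angular window: fall back to the central slice with a warning
  ts40 <- simulate_tilt_series(v, c(-40, 40))
  expect_warning(prf <- extract_pair(v, ts40, c(20, 20, 10), 9, 15),
                 "P_s-only")
  expect_equal(prf$P_t, prf$P_s)

  # absent tilt series: silent P_s-only mode
  prn <- extract_pair(v, NULL, c(20, 20, 10), 9)
  expect_equal(prn$P_t, prn$P_s)

  # border coordinate: reflect-padded and flagged
  prb <- extract_pair(v, NULL, c(1, 1, 10), 9)
  expect_true(prb$border_flagged)
  expect_true(all(is.finite(prb$P_s)))
})

test_that("candidate recall on the clean study scene is complete", {
  sc <- study_scene()
  res <- propose_candidates(sc$clean, default_config())
  rep <- evaluate_detection(res$coords, sc$ground_truth$spheres, 4)
  expect_equal(rep$recall, 1)
})
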