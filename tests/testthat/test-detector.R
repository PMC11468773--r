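tiny_det_cfg <- function() {
  cfg <- default_config()
  cfg$crop_xy <- 32L
  cfg$crop_z <- 5L
  cfg$unet_channels <- 4L
  cfg$fusion_channels <- 8L
  cfg$contrast_channels <- 8L
  cfg$detect_epochs <- 2L
  cfg$steps_per_epoch <- 4L
  cfg$contrast_subsample <- 32L
  cfg$pi_p <- 0.1
  cfg
}

tiny_scene <- function() {
  fixture("tiny_det_scene", function()
    render_scene(scene_spec(shape = c(32L, 32L, 16L), n_spheres = 8L,
                            sphere_radius = 3, noise_sigma = 0.3,
                            wedge_half_angle = 70, seed = 5L)))
}

test_that("detector forward produces aligned heat and feature maps", {
  cfg <- tiny_det_cfg()
  m <- tomomine:::init_detector(cfg)
  x <- array(rnorm(32 * 32 * 5), c(32, 32, 5))
  f <- tomomine:::detector_forward(m, x)
  expect_equal(dim(f$yhat), c(32, 32, 5))
  expect_true(all(f$yhat > 0 & f$yhat < 1))
  expect_equal(dim(f$F), c(32, 32, 5, 8))
  expect_error(tomomine:::detector_forward(m, array(0, c(32, 32, 2))),
               "receptive")
  expect_error(tomomine:::detector_forward(m, array(0, c(30, 30, 5))),
               "divisible")
})

test_that("detector end-to-end gradients match finite differences", {
  cfg <- tiny_det_cfg()
  cfg$crop_xy <- 8L
  m <- tomomine:::init_detector(cfg)
  set.seed(3)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  gy <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  loss_of <- function(model) sum(tomomine:::detector_forward(model, x)$logits * gy)
  f <- tomomine:::detector_forward(m, x)
  gr <- tomomine:::detector_backward(m, f$caches, gy)
  eps <- 1e-5
  # probe a handful of parameters across layers
  assign_in <- function(params, path, value) {
    if (length(path) == 1) { params[[path[[1]]]] <- value; return(params) }
    params[[path[[1]]]] <- assign_in(params[[path[[1]]]], path[-1], value)
    params
  }
  probes <- list(list("fusion", "w"), list("center_w"),
                 list("bott", "c1", "w"), list("enc", 1L, "c1", "w"))
  for (pr in probes) {
    for (idx in c(1L, 3L)) {
      vplus <- Reduce(`[[`, pr, m$params); vplus[idx] <- vplus[idx] + eps
      vminus <- Reduce(`[[`, pr, m$params); vminus[idx] <- vminus[idx] - eps
      mplus <- m; mplus$params <- assign_in(m$params, pr, vplus)
      mminus <- m; mminus$params <- assign_in(m$params, pr, vminus)
      fd <- (loss_of(mplus) - loss_of(mminus)) / (2 * eps)
      expect_equal(Reduce(`[[`, pr, gr)[idx], fd, tolerance = 1e-4)
    }
  }
})

test_that("training contracts: lr 0 freezes, same seed reproduces", {
  sc <- tiny_scene()
  ann <- sc$ground_truth$spheres[1:4, ]
  cfg <- tiny_det_cfg()
  cfg$detect_lr <- 0
  cfg$detect_epochs <- 1L
  cfg$steps_per_epoch <- 2L
  m0 <- train_detector(sc$volume, ann, cfg)
  init <- tomomine:::init_detector(cfg)
  expect_equal(m0$params, init$params, tolerance = 1e-12)

  cfg$detect_lr <- 1e-3
  m1 <- train_detector(sc$volume, ann, cfg)
  m2 <- train_detector(sc$volume, ann, cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_error(train_detector(sc$volume, coord_table(), cfg), "empty")
})

test_that("short training raises heat at labeled centers above background", {
  sc <- tiny_scene()
  gt <- sc$ground_truth$spheres
  ann <- gt[1:4, ]
  cfg <- tiny_det_cfg()
  cfg$detect_lr <- 3e-3
  cfg$detect_epochs <- 3L
  cfg$steps_per_epoch <- 6L
  m <- train_detector(sc$volume, ann, cfg)
  expect_lt(mean(tail(m$loss_history, 4)), mean(head(m$loss_history, 4)))
  hm <- predict_heatmap(m, sc$volume)
  expect_identical(predict_heatmap(m, sc$volume), hm)   # determinism
  ci <- cbind(floor(gt$x), floor(gt$y), floor(gt$z)) + 1
  set.seed(1)
  bg <- hm[cbind(sample(32, 100, TRUE), sample(32, 100, TRUE),
                 sample(16, 100, TRUE))]
  expect_gt(mean(hm[ci]), mean(bg))
})

test_that("ablation flags change the optimized objective", {
  sc <- tiny_scene()
  ann <- sc$ground_truth$spheres[1:4, ]
  cfg <- tiny_det_cfg()
  cfg$detect_epochs <- 1L
  cfg$steps_per_epoch <- 2L
  m_full <- train_detector(sc$volume, ann, cfg)
  cfg2 <- cfg; cfg2$ablate_pu <- TRUE
  m_pu <- train_detector(sc$volume, ann, cfg2)
  cfg3 <- cfg; cfg3$ablate_contrastive <- TRUE
  m_con <- train_detector(sc$volume, ann, cfg3)
  expect_false(identical(m_full$loss_history, m_pu$loss_history))
  expect_false(identical(m_full$loss_history, m_con$loss_history))
})
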