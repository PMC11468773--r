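test_that("a single noise-free sphere renders as one extremum at its center", {
  sp <- scene_spec(shape = c(32L, 32L, 32L), n_spheres = 1L,
                   sphere_radius = 4, wedge_half_angle = 90,
                   noise_sigma = 0, seed = 2L)
  sc <- render_scene(sp)
  v <- sc$volume$voxels
  ctr <- unlist(sc$ground_truth$spheres[1, c("x", "y", "z")])
  # particles are dark: the unique minimum sits at the ground-truth center
  mins <- which(v == min(v), arr.ind = TRUE)
  expect_equal(nrow(mins), 1L)
  expect_lt(sqrt(sum((mins[1, ] - 1 - ctr)^2)), 1)
})

test_that("an empty noise-free scene is a constant background", {
  sc <- render_scene(scene_spec(n_spheres = 0L, noise_sigma = 0,
                                wedge_half_angle = 90))
  expect_equal(diff(range(sc$volume$voxels)), 0)
})

test_that("rendering is bit-identical for a fixed seed", {
  sp <- scene_spec(seed = 11L)
  expect_identical(render_scene(sp)$volume$voxels,
                   render_scene(sp)$volume$voxels)
})

test_that("ground-truth centers are recoverable from the clean render", {
  sc <- study_scene()
  inv <- 1 - sc$clean$voxels
  resp <- dog_response(inv, dog_sigma_ladder(4))
  cand <- nms_3d(resp, radius = 4, threshold = auto_threshold(resp))
  rep <- evaluate_detection(cand, sc$ground_truth$spheres, 4)
  expect_equal(rep$recall, 1)
})

test_that("tilt projection at 0 degrees equals the z-sum", {
  v <- array(runif(16 * 12 * 8), c(16, 12, 8))
  ts <- simulate_tilt_series(v, 0)
  expect_equal(ts$images[[1]], apply(v, c(1, 2), sum), tolerance = 1e-12)
})

test_that("a point source projects to the predicted tilted position", {
  v <- array(0, c(100, 10, 60))
  v[71, 6, 41] <- 1   # 0-based (70, 5, 40)
  ts <- simulate_tilt_series(v, c(0, 30))
  pk0 <- which(ts$images[[1]] == max(ts$images[[1]]), arr.ind = TRUE) - 1
  expect_equal(unname(pk0[1, ]), c(70, 5))
  # independent evaluation of the projection formula
  th <- 30 * pi / 180
  x_expect <- (70 - 50) * cos(th) + (40 - 30) * sin(th) + 50
  im <- ts$images[[2]]
  pk <- which(im == max(im), arr.ind = TRUE) - 1
  expect_lt(abs(pk[1, 1] - x_expect), 1)
  expect_equal(unname(pk[1, 2]), 5)
})

test_that("missing wedge: identity at 90 degrees, idempotent, z-elongation", {
  v <- array(rnorm(16^3), c(16, 16, 16))
  expect_equal(apply_missing_wedge(v, 90), v, tolerance = 1e-10)
  cst <- array(3, c(8, 8, 8))
  expect_equal(apply_missing_wedge(cst, 45), cst, tolerance = 1e-10)

  s <- array(0, c(32, 32, 32))
  s <- tomomine:::splat_ball(s, c(15, 15, 15), 5, -1)  # bright ball
  w1 <- apply_missing_wedge(s, 60)
  expect_equal(apply_missing_wedge(w1, 60), w1, tolerance = 1e-10)
  fwhm <- function(p) sum(p >= max(p) / 2)
  expect_gte(fwhm(w1[16, 16, ]), fwhm(w1[, 16, 16]))
})

test_that("noise scaling and determinism follow the spec'd contract", {
  v <- array(0.5, c(32, 32, 32))
  expect_identical(add_noise(v, 0), v)
  n1 <- add_noise(v, 0.1, seed = 1)
  # constant volume: unit signal scale, nominal sd = 0.1
  expect_lt(abs(sd(n1) - 0.1) / 0.1, 0.05)
  n2 <- add_noise(v, 0.1, seed = 2)
  expect_false(identical(n1, n2))
  se <- 0.1 / sqrt(length(v))
  expect_lt(abs(mean(n1) - mean(n2)), 3 * sqrt(2) * se)
  expect_identical(add_noise(v, 0.1, seed = 1), n1)
})

test_that("impossible placement requests raise a placement error", {
  expect_error(render_scene(scene_spec(shape = c(12L, 12L, 12L),
                                       n_spheres = 200L)),
               "placement error")
})

test_that("tube centerlines follow their generating quadratics", {
  sc <- two_class_scene()
  for (tb in sc$ground_truth$tubes) {
    cf <- tb$coefficients
    ys <- tb$centerline[, "y"]
    expect_equal(tb$centerline[, "x"],
                 unname(cf["a0"] + cf["b0"] * ys + cf["c0"] * ys^2),
                 tolerance = 1e-10)
    expect_equal(tb$centerline[, "z"],
                 unname(cf["a1"] + cf["b1"] * ys + cf["c1"] * ys^2),
                 tolerance = 1e-10)
  }
})
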