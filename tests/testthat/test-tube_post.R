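test_that("distance grouping separates clusters and keeps chains together", {
  far <- coord_table("t", c(0, 1, 50, 51), c(0, 0, 0, 0), c(0, 0, 0, 0))
  g <- group_by_distance(far, cutoff = 2)
  expect_length(g, 2L)
  expect_equal(g[[1]], c(1L, 2L))

  chain <- coord_table("t", seq(0, 18, by = 1.8), rep(0, 11), rep(0, 11))
  expect_length(group_by_distance(chain, cutoff = 2), 1L)
})

test_that("grouping matches a union-find oracle on random points", {
  for (seed in 1:3) {
    set.seed(seed)
    pts <- coord_table("t", runif(50, 0, 30), runif(50, 0, 30),
                       runif(50, 0, 30))
    got <- group_by_distance(pts, 6)
    want <- oracle_groups(pts, 6)
    expect_equal(lapply(got, as.integer), lapply(want, as.integer))
  }
})

test_that("exact quadratics are recovered with vanishing residual", {
  ys <- seq(0, 20, by = 1)
  tab <- coord_table("t", 1 + 2 * ys + 0.1 * ys^2, ys, rep(3, length(ys)))
  m <- fit_tube(tab)
  expect_equal(unname(m$coefficients[c("a0", "b0", "c0")]), c(1, 2, 0.1),
               tolerance = 1e-8)
  expect_equal(unname(m$coefficients[c("a1", "b1", "c1")]), c(3, 0, 0),
               tolerance = 1e-8)
  expect_lt(m$residual, 1e-8)

  line <- coord_table("t", ys, ys, ys)
  ml <- fit_tube(line)
  expect_lt(abs(ml$coefficients["c0"]), 1e-8)
  expect_lt(ml$residual, 1e-8)
  expect_equal(ml$max_curvature, 0, tolerance = 1e-8)
})

test_that("rejection reasons distinguish short and degenerate groups", {
  short <- coord_table("t", 1:4, 1:4, 1:4)
  m <- fit_tube(short)
  expect_s3_class(m, "tube_rejection")
  expect_equal(m$reason, "too short")
  flat <- coord_table("t", 1:8, rep(2, 8), 1:8)
  m2 <- fit_tube(flat)
  expect_s3_class(m2, "tube_rejection")
  expect_equal(m2$reason, "not y-parameterizable")
})

test_that("noisy quadratic coefficients land within three standard errors", {
  set.seed(12)
  ys <- seq(0, 39, by = 1)
  truth <- c(a0 = 5, b0 = 0.8, c0 = 0.02)
  xs <- truth["a0"] + truth["b0"] * ys + truth["c0"] * ys^2 + rnorm(40, sd = 0.5)
  tab <- coord_table("t", xs, ys, rep(1, 40))
  m <- fit_tube(tab)
  fit <- lm(xs ~ ys + I(ys^2))
  se <- summary(fit)$coefficients[, "Std. Error"]
  for (i in 1:3)
    expect_lt(abs(m$coefficients[i] - truth[i]), 3 * se[i] + 1e-9)
})

test_that("maximum curvature matches the closed form and a finer grid", {
  ys <- seq(-1, 1, by = 0.05)
  par_tab <- coord_table("t", ys^2, ys, rep(0, length(ys)))
  m <- fit_tube(par_tab)
  # x = y^2: kappa(0) = 2 is the maximum on [-1, 1]
  expect_equal(m$max_curvature, 2, tolerance = 1e-3)

  fine <- tube_max_curvature(m, step = 0.001)
  coarse <- tube_max_curvature(m, step = 0.1)
  expect_lt(abs(fine - coarse), 1e-3)
})

test_that("resampling walks y in steps of 2 and stays on the curve", {
  ys <- seq(0, 10, by = 0.5)
  tab <- coord_table("t", 2 + 0.5 * ys + 0.05 * ys^2, ys, 4 + 0.1 * ys)
  m <- fit_tube(tab)
  rs <- resample_tube(m, step = 2)
  expect_equal(rs$y, seq(0, 10, by = 2))
  expect_equal(nrow(rs), floor((10 - 0) / 2) + 1)
  expect_equal(rs$x, 2 + 0.5 * rs$y + 0.05 * rs$y^2, tolerance = 1e-8)
  expect_equal(rs$z, 4 + 0.1 * rs$y, tolerance = 1e-8)

  m1 <- m; m1$y_range <- c(3, 3)
  expect_equal(nrow(resample_tube(m1)), 1L)
  m2 <- m; m2$y_range <- c(5, 4)
  expect_equal(nrow(resample_tube(m2)), 0L)
})

test_that("tube filtering applies strict residual and curvature cutoffs", {
  mk <- function(res, curv) structure(list(residual = res,
                                           max_curvature = curv),
                                      class = "tube_model")
  ms <- list(mk(0, 0), mk(0.5, 0.05), mk(1.5, 0.01), mk(0.1, 0.1))
  kept <- filter_tubes(ms, residual_cutoff = 1.5, curvature_cutoff = 0.1)
  want <- vapply(ms, function(m) m$residual < 1.5 && m$max_curvature < 0.1,
                 logical(1))
  expect_equal(length(kept), sum(want))
  expect_length(filter_tubes(list(mk(0.2, 0.1)), 1, 0.1), 0L)  # at cutoff
})

test_that("jittered ground-truth centerlines are recovered end to end", {
  sc <- two_class_scene()
  tubes <- sc$ground_truth$tubes
  set.seed(20)
  pts <- NULL
  for (tb in tubes) {
    cl <- tb$centerline[seq(1, nrow(tb$centerline), by = 4), ]
    jit <- cl + matrix(runif(length(cl), -1, 1) * 0.2, nrow(cl), 3)
    pts <- rbind(pts, jit)
  }
  det <- coord_table("t", pts[, 1], pts[, 2], pts[, 3])
  res <- trace_tubes(det, cutoff = 6, residual_cutoff = 1.5,
                     curvature_cutoff = 0.1, step = 2)
  expect_equal(length(res$tubes), length(tubes))
  # resampled points lie within 1 voxel RMS of the generating curves
  for (i in seq_along(res$tubes)) {
    rs <- res$coords[res$coords$label == i, ]
    errs <- vapply(seq_len(nrow(rs)), function(j) {
      best <- Inf
      for (tb in tubes) {
        cf <- tb$coefficients
        xe <- cf["a0"] + cf["b0"] * rs$y[j] + cf["c0"] * rs$y[j]^2
        ze <- cf["a1"] + cf["b1"] * rs$y[j] + cf["c1"] * rs$y[j]^2
        best <- min(best, (rs$x[j] - xe)^2 + (rs$z[j] - ze)^2)
      }
      best
    }, numeric(1))
    expect_lt(sqrt(mean(errs)), 1)
  }
})
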