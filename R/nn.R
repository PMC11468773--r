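# Minimal neural-network layers with explicit forward/backward passes.
# Convolutions run through the compiled im2col/GEMM kernels in src/; fully
# connected and batch-norm layers are plain matrix code. All parameter
# initialization draws from R's RNG so training is deterministic given a seed.

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

conv2d_make <- function(k, cin, cout) {
  list(w = he_init(c(k, k, cin, cout), k * k * cin), b = numeric(cout))
}

conv3d_make <- function(cin, cout) {
  list(w = he_init(c(3, 3, 3, cin, cout), 27 * cin), b = numeric(cout))
}

tconv2_make <- function(cin, cout) {
  list(w = he_init(c(2, 2, cin, cout), 4 * cin), b = numeric(cout))
}

fc_make <- function(din, dout) {
  list(w = he_init(c(din, dout), din), b = numeric(dout))
}

fc_fw <- function(x, p) x %*% p$w + matrix(p$b, nrow(x), length(p$b),
                                           byrow = TRUE)

fc_bw <- function(x, p, gy) {
  list(gx = gy %*% t(p$w), gw = t(x) %*% gy, gb = colSums(gy))
}

bn1d_make <- function(d) {
  list(gamma = rep(1, d), beta = numeric(d))
}

bn1d_stats_make <- function(d) {
  list(mean = numeric(d), var = rep(1, d))
}

# running statistics are threaded separately so they never enter the
# optimizer's parameter tree
bn1d_fw <- function(x, p, stats, training, momentum = 0.1, eps = 1e-5) {
  if (training && nrow(x) > 1) {
    mu <- colMeans(x)
    va <- colMeans(x^2) - mu^2
    stats$mean <- (1 - momentum) * stats$mean + momentum * mu
    stats$var <- (1 - momentum) * stats$var + momentum * va
  } else {
    mu <- stats$mean
    va <- stats$var
  }
  xc <- sweep(x, 2, mu)
  istd <- 1 / sqrt(va + eps)
  xh <- sweep(xc, 2, istd, "*")
  y <- sweep(xh, 2, p$gamma, "*")
  y <- sweep(y, 2, p$beta, "+")
  list(y = y, cache = list(xh = xh, istd = istd, training = training),
       stats = stats)
}

bn1d_bw <- function(p, cache, gy) {
  xh <- cache$xh
  n <- nrow(xh)
  ggamma <- colSums(gy * xh)
  gbeta <- colSums(gy)
  gxh <- sweep(gy, 2, p$gamma, "*")
  if (cache$training && n > 1) {
    gx <- sweep(gxh - matrix(colMeans(gxh), n, ncol(xh), byrow = TRUE) -
                xh * matrix(colMeans(gxh * xh), n, ncol(xh), byrow = TRUE),
                2, cache$istd, "*")
  } else {
    gx <- sweep(gxh, 2, cache$istd, "*")
  }
  list(gx = gx, gamma = ggamma, beta = gbeta)
}

relu_fw <- function(x) {
  list(y = pmax(x, 0), mask = x > 0)
}

relu_bw <- function(mask, gy) {
  gy * mask
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---------------------------------------------------------------------------
# optimizers: parameters and gradients are nested lists of arrays

tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    out
  } else f(a, b)
}

tree_zero_like <- function(a) {
  if (is.list(a)) lapply(a, tree_zero_like)
  else if (is.null(dim(a))) numeric(length(a))
  else array(0, dim = dim(a))
}

sgd_make <- function(params) {
  list(vel = tree_zero_like(params))
}

sgd_step <- function(params, grads, state, lr, momentum = 0.9,
                     weight_decay = 0) {
  step1 <- function(p, pair) {
    g <- pair$g + weight_decay * p
    v <- momentum * pair$v + g
    list(p = p - lr * v, v = v)
  }
  walk <- function(p, g, v) {
    if (is.list(p)) {
      res <- mapply(walk, p, g, v, SIMPLIFY = FALSE)
      list(p = lapply(res, `[[`, "p"), v = lapply(res, `[[`, "v"))
    } else step1(p, list(g = g, v = v))
  }
  res <- walk(params, grads, state$vel)
  list(params = res$p, state = list(vel = res$v))
}

adam_make <- function(params) {
  list(m = tree_zero_like(params), v = tree_zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      res <- mapply(walk, p, g, m, v, SIMPLIFY = FALSE)
      list(p = lapply(res, `[[`, "p"), m = lapply(res, `[[`, "m"),
           v = lapply(res, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      list(p = p - lr * (m / bc1) / (sqrt(v / bc2) + eps), m = m, v = v)
    }
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = state$t))
}

tree_add <- function(a, b) tree_map2(a, b, `+`)
tree_scale <- function(a, s) {
  if (is.list(a)) lapply(a, tree_scale, s = s) else a * s
}

bn_identity <- function(d) list(gamma = rep(1, d), beta = numeric(d))
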