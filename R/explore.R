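#' Augmentation policy for patch pairs
#'
#' Brightness jitter is drawn from \[0, `brightness_max`\] (default 0.5),
#' contrast jitter from \[0, `contrast_max`\] (default 0.2), random
#' resize-crop keeps between `crop_scale_min` (default 0.7) and 1 times the
#' original side, corner dropout zeroes a square of side between the two
#' `corner_frac` fractions of the patch at a random corner, and rotations
#' are restricted to multiples of 90 degrees (no interpolation artifacts).
#'
#' @param flip_prob probability of each of horizontal/vertical flip.
#' @param brightness_max,contrast_max jitter amplitude bounds.
#' @param crop_scale_min lower bound of the resize-crop scale.
#' @param corner_prob probability of applying corner dropout.
#' @param corner_frac (min, max) dropout square side as a patch fraction.
#' @param rotate90 draw a rotation from \{0, 90, 180, 270\} degrees.
#' @return a list of class `augment_policy`.
#' @export
augment_policy <- function(flip_prob = 0.5, brightness_max = 0.5,
                           contrast_max = 0.2, crop_scale_min = 0.7,
                           corner_prob = 0.5, corner_frac = c(0.1, 0.25),
                           rotate90 = TRUE) {
  structure(as.list(environment()), class = "augment_policy")
}

identity_policy <- function() {
  augment_policy(flip_prob = 0, brightness_max = 0, contrast_max = 0,
                 crop_scale_min = 1, corner_prob = 0, rotate90 = FALSE)
}

rot90_mat <- function(m, k) {
  k <- k %% 4
  if (k == 0) return(m)
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

resize_bilinear <- function(m, side) {
  n <- nrow(m)
  if (n == side) return(m)
  g <- seq(0, n - 1, length.out = side)
  bilinear_sample(m, g, g)
}

#' Randomly augment a patch pair
#'
#' The same spatial transform (resize-crop, flips, 90-degree rotation,
#' corner dropout) and the same intensity jitter are applied to both P_t and
#' P_s of the view, preserving their correspondence. Deterministic given
#' `seed`; output shape equals input shape.
#'
#' @param pair a `patch_pair` from [extract_pair()].
#' @param policy an [augment_policy()].
#' @param seed RNG seed.
#' @return an augmented `patch_pair`.
#' @export
augment_pair <- function(pair, policy = augment_policy(), seed = 0L) {
  set.seed(seed)
  s <- pair$side
  draw <- list(
    scale = runif(1, policy$crop_scale_min, 1),
    cx = runif(2),                       # crop offsets (relative)
    fh = runif(1) < policy$flip_prob,
    fv = runif(1) < policy$flip_prob,
    rot = if (policy$rotate90) sample(0:3, 1) else 0L,
    bright = runif(1, -policy$brightness_max, policy$brightness_max),
    contr = runif(1, -policy$contrast_max, policy$contrast_max),
    do_corner = runif(1) < policy$corner_prob,
    corner = sample(1:4, 1),
    cfrac = runif(1, policy$corner_frac[1], policy$corner_frac[2]))
  tf <- function(m) {
    if (draw$scale < 1) {
      cs <- max(2L, round(draw$scale * s))
      x0 <- floor(draw$cx[1] * (s - cs))
      y0 <- floor(draw$cx[2] * (s - cs))
      m <- resize_bilinear(m[x0 + seq_len(cs), y0 + seq_len(cs)], s)
    }
    if (draw$fh) m <- m[rev(seq_len(s)), , drop = FALSE]
    if (draw$fv) m <- m[, rev(seq_len(s)), drop = FALSE]
    m <- rot90_mat(m, draw$rot)
    m <- m * (1 + draw$bright)
    mu <- mean(m)
    m <- mu + (1 + draw$contr) * (m - mu)
    if (draw$do_corner) {
      cs <- max(1L, round(draw$cfrac * s))
      ix <- if (draw$corner %in% c(1, 2)) seq_len(cs) else s - cs + seq_len(cs)
      iy <- if (draw$corner %in% c(1, 3)) seq_len(cs) else s - cs + seq_len(cs)
      m[ix, iy] <- 0
    }
    m
  }
  out <- pair
  out$P_t <- tf(pair$P_t)
  out$P_s <- tf(pair$P_s)
  out
}

#' Negative cosine similarity
#'
#' D(y, z) = -(y / ||y||) . (z / ||z||), in \[-1, 1\].
#'
#' @param y,z nonzero numeric vectors of equal length.
#' @return scalar.
#' @export
negative_cosine <- function(y, z) {
  ny <- sqrt(sum(y^2)); nz <- sqrt(sum(z^2))
  if (ny == 0 || nz == 0) stop("negative_cosine is undefined for zero vectors")
  -sum(y * z) / (ny * nz)
}

#' Symmetrized stop-gradient contrastive loss
#'
#' L = D(y1, stopgrad z2)/2 + D(y2, stopgrad z1)/2 with D the negative
#' cosine similarity; minimum -1, attained when each prediction is
#' positively parallel to its paired (constant) target. The z arguments are
#' treated as constants during back-propagation: [symmetrized_loss_grads()]
#' returns exactly zero for them.
#'
#' @param y1,y2 predictor outputs of the two views.
#' @param z1,z2 projector outputs of the two views (stop-gradient side).
#' @return scalar loss in \[-1, 1\].
#' @export
symmetrized_loss <- function(y1, z2, y2, z1) {
  0.5 * negative_cosine(y1, z2) + 0.5 * negative_cosine(y2, z1)
}

neg_cosine_grad_y <- function(y, z) {
  ny <- sqrt(sum(y^2)); nz <- sqrt(sum(z^2))
  yh <- y / ny; zh <- z / nz
  -(zh - sum(yh * zh) * yh) / ny
}

#' Gradients of the symmetrized loss (stop-gradient contract)
#'
#' @inheritParams symmetrized_loss
#' @return list with `gy1`, `gy2` (analytic gradients) and `gz1`, `gz2`
#'   (identically zero by the stop-gradient rule).
#' @export
symmetrized_loss_grads <- function(y1, z2, y2, z1) {
  list(gy1 = 0.5 * neg_cosine_grad_y(y1, z2),
       gy2 = 0.5 * neg_cosine_grad_y(y2, z1),
       gz1 = numeric(length(z1)), gz2 = numeric(length(z2)))
}

# ---------------------------------------------------------------------------
# exploration model: configurable-depth residual 2D backbone + 3-layer
# projection MLP (the encoder f) and 2-layer prediction MLP (h), output 128.

init_exploration_model <- function(cfg = default_config()) {
  set.seed(cfg$seed)
  S <- cfg$backbone_stages
  c0 <- cfg$backbone_channels
  chans <- c0 * 2^(0:(S - 1))
  stages <- list()
  cin <- c0
  for (s in seq_len(S)) {
    stages[[s]] <- list(
      proj = conv2d_make(1L, cin, chans[s]),
      res1 = conv2d_make(3L, chans[s], chans[s]),
      res2 = conv2d_make(3L, chans[s], chans[s]))
    cin <- chans[s]
  }
  dlast <- chans[S]
  params <- list(
    stem = conv2d_make(3L, 2L, c0),
    stages = stages,
    proj_fc1 = fc_make(dlast, cfg$embed_dim), proj_bn1 = bn1d_make(cfg$embed_dim),
    proj_fc2 = fc_make(cfg$embed_dim, cfg$embed_dim),
    proj_bn2 = bn1d_make(cfg$embed_dim),
    proj_fc3 = fc_make(cfg$embed_dim, cfg$embed_dim),
    pred_fc1 = fc_make(cfg$embed_dim, cfg$embed_dim %/% 2L),
    pred_bn1 = bn1d_make(cfg$embed_dim %/% 2L),
    pred_fc2 = fc_make(cfg$embed_dim %/% 2L, cfg$embed_dim))
  bn_stats <- list(proj_bn1 = bn1d_stats_make(cfg$embed_dim),
                   proj_bn2 = bn1d_stats_make(cfg$embed_dim),
                   proj_bn3 = bn1d_stats_make(cfg$embed_dim),
                   pred_bn1 = bn1d_stats_make(cfg$embed_dim %/% 2L))
  structure(list(params = params, bn_stats = bn_stats, cfg = cfg,
                 loss_history = numeric()),
            class = "exploration_model")
}

pair_to_input <- function(pair) {
  std <- function(m) {
    s <- sd(m)
    if (s > 0) (m - mean(m)) / s else m - mean(m)
  }
  x <- array(0, dim = c(nrow(pair$P_t), ncol(pair$P_t), 2L))
  x[, , 1] <- std(pair$P_t)
  x[, , 2] <- std(pair$P_s)
  x
}

# backbone forward for one sample; returns pooled feature vector + caches
backbone_fw <- function(params, x) {
  caches <- list()
  h <- cpp_conv2d_fw(x, params$stem$w, params$stem$b)
  r <- relu_fw(h)
  caches$stem <- list(x = x, mask = r$mask)
  h <- r$y
  for (s in seq_along(params$stages)) {
    st <- params$stages[[s]]
    pin <- h
    h <- cpp_conv2d_fw(h, st$proj$w, st$proj$b)
    rp <- relu_fw(h)
    rin <- rp$y
    c1 <- cpp_conv2d_fw(rin, st$res1$w, st$res1$b)
    r1 <- relu_fw(c1)
    c2 <- cpp_conv2d_fw(r1$y, st$res2$w, st$res2$b)
    sum_ <- rin + c2
    r2 <- relu_fw(sum_)
    mp <- cpp_maxpool2_fw(r2$y)
    caches$stages[[s]] <- list(pin = pin, pmask = rp$mask, rin = rin,
                               r1in = c1, r1mask = r1$mask, r1out = r1$y,
                               r2mask = r2$mask, mp_idx = mp$idx,
                               mp_in_dim = dim(r2$y))
    h <- mp$y
  }
  d <- dim(h)
  pooled <- apply(h, 3, mean)
  caches$pool_dim <- d
  list(feat = pooled, caches = caches)
}

backbone_bw <- function(params, caches, gfeat) {
  d <- caches$pool_dim
  gh <- array(rep(gfeat, each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
  grads <- list(stem = NULL, stages = vector("list",
                                             length(params$stages)))
  for (s in rev(seq_along(params$stages))) {
    st <- params$stages[[s]]
    ca <- caches$stages[[s]]
    gh <- cpp_maxpool2_bw(ca$mp_idx, gh, as.integer(ca$mp_in_dim))
    gh <- relu_bw(ca$r2mask, gh)
    # residual: gh flows to both rin and the conv path
    bw2 <- cpp_conv2d_bw(ca$r1out, st$res2$w, gh)
    g1 <- relu_bw(ca$r1mask, bw2$gx)
    bw1 <- cpp_conv2d_bw(ca$rin, st$res1$w, g1)
    grin <- gh + bw1$gx
    grin <- relu_bw(ca$pmask, grin)
    bwp <- cpp_conv2d_bw(ca$pin, st$proj$w, grin)
    grads$stages[[s]] <- list(
      proj = list(w = bwp$gw, b = bwp$gb),
      res1 = list(w = bw1$gw, b = bw1$gb),
      res2 = list(w = bw2$gw, b = bw2$gb))
    gh <- bwp$gx
  }
  gh <- relu_bw(caches$stem$mask, gh)
  bws <- cpp_conv2d_bw(caches$stem$x, params$stem$w, gh)
  grads$stem <- list(w = bws$gw, b = bws$gb)
  grads
}

# encoder (backbone + projector) and predictor on a batch of inputs;
# returns z (projector out), y (predictor out) and caches for backward
explore_forward <- function(model, inputs, training = FALSE,
                            bn3_batch = training) {
  params <- model$params
  bb <- lapply(inputs, function(x) backbone_fw(params, x))
  feat <- do.call(rbind, lapply(bb, `[[`, "feat"))
  h1 <- fc_fw(feat, params$proj_fc1)
  b1 <- bn1d_fw(h1, params$proj_bn1, model$bn_stats$proj_bn1, training)
  model$bn_stats$proj_bn1 <- b1$stats
  r1 <- relu_fw(b1$y)
  h2 <- fc_fw(r1$y, params$proj_fc2)
  b2 <- bn1d_fw(h2, params$proj_bn2, model$bn_stats$proj_bn2, training)
  model$bn_stats$proj_bn2 <- b2$stats
  r2 <- relu_fw(b2$y)
  z_pre <- fc_fw(r2$y, params$proj_fc3)
  # non-affine output normalization guards against representational collapse
  b3 <- bn1d_fw(z_pre, bn_identity(ncol(z_pre)), model$bn_stats$proj_bn3,
                training || bn3_batch)
  model$bn_stats$proj_bn3 <- b3$stats
  z <- b3$y
  p1 <- fc_fw(z, params$pred_fc1)
  pb1 <- bn1d_fw(p1, params$pred_bn1, model$bn_stats$pred_bn1, training)
  model$bn_stats$pred_bn1 <- pb1$stats
  pr1 <- relu_fw(pb1$y)
  y <- fc_fw(pr1$y, params$pred_fc2)
  list(z = z, y = y, model = model,
       caches = list(bb = bb, feat = feat, h1 = h1, b1 = b1, r1 = r1,
                     h2 = h2, b2 = b2, r2 = r2, z_pre = z_pre, b3 = b3,
                     z = z, p1 = p1, pb1 = pb1, pr1 = pr1))
}

# backward from gy (grad w.r.t. predictor output) and gz (grad w.r.t.
# projector output, i.e. arriving from elsewhere than the predictor)
explore_backward <- function(model, caches, gy, gz_extra = NULL) {
  params <- model$params
  gr <- list()
  bw <- fc_bw(caches$pr1$y, params$pred_fc2, gy)
  gr$pred_fc2 <- list(w = bw$gw, b = bw$gb)
  g <- relu_bw(caches$pr1$mask, bw$gx)
  bnb <- bn1d_bw(params$pred_bn1, caches$pb1$cache, g)
  gr$pred_bn1 <- list(gamma = bnb$gamma, beta = bnb$beta)
  bw <- fc_bw(caches$z, params$pred_fc1, bnb$gx)
  gr$pred_fc1 <- list(w = bw$gw, b = bw$gb)
  gz <- bw$gx
  if (!is.null(gz_extra)) gz <- gz + gz_extra
  bnb <- bn1d_bw(bn_identity(ncol(gz)), caches$b3$cache, gz)
  bw <- fc_bw(caches$r2$y, params$proj_fc3, bnb$gx)
  gr$proj_fc3 <- list(w = bw$gw, b = bw$gb)
  g <- relu_bw(caches$r2$mask, bw$gx)
  bnb <- bn1d_bw(params$proj_bn2, caches$b2$cache, g)
  gr$proj_bn2 <- list(gamma = bnb$gamma, beta = bnb$beta)
  bw <- fc_bw(caches$r1$y, params$proj_fc2, bnb$gx)
  gr$proj_fc2 <- list(w = bw$gw, b = bw$gb)
  g <- relu_bw(caches$r1$mask, bw$gx)
  bnb <- bn1d_bw(params$proj_bn1, caches$b1$cache, g)
  gr$proj_bn1 <- list(gamma = bnb$gamma, beta = bnb$beta)
  bw <- fc_bw(caches$feat, params$proj_fc1, bnb$gx)
  gr$proj_fc1 <- list(w = bw$gw, b = bw$gb)
  gfeat <- bw$gx
  bbg <- NULL
  for (i in seq_along(caches$bb)) {
    g1 <- backbone_bw(params, caches$bb[[i]]$caches, gfeat[i, ])
    bbg <- if (is.null(bbg)) g1 else tree_add(bbg, g1)
  }
  gr$stem <- bbg$stem
  gr$stages <- bbg$stages
  # order the gradient tree exactly like the parameter tree
  gr[names(params)]
}

#' Train the contrastive exploration network
#'
#' Stochastic-gradient training of the Siamese encoder on two randomly
#' augmented views per patch pair, minimizing the symmetrized negative
#' cosine similarity with stop-gradient on the projector branch. SGD with
#' momentum, weight decay and a cosine-decayed learning rate. Deterministic
#' given `cfg$seed`. The default configuration is the CPU-scaled profile
#' (2 residual stages, batch 16, 30 steps); the full-scale recipe (batch
#' 256, learning rate 0.02, 300 epochs) is reachable through the same
#' configuration keys.
#'
#' @param pairs list of `patch_pair`s (at least 2).
#' @param cfg a [default_config()]-style configuration.
#' @param policy an [augment_policy()].
#' @return an `exploration_model` with a recorded `loss_history`.
#' @export
train_exploration <- function(pairs, cfg = default_config(),
                              policy = augment_policy()) {
  if (length(pairs) == 0) stop("empty dataset")
  if (length(pairs) < 2) stop("need at least 2 patch pairs")
  model <- init_exploration_model(cfg)
  set.seed(cfg$seed + 1L)
  state <- sgd_make(model$params)
  n_steps <- cfg$explore_steps
  batch <- min(cfg$explore_batch, length(pairs))
  for (step in seq_len(n_steps)) {
    lr <- cfg$explore_lr * 0.5 * (1 + cos(pi * (step - 1) / n_steps))
    idx <- sample(seq_along(pairs), batch,
                  replace = batch > length(pairs))
    seeds <- sample.int(.Machine$integer.max - 1L, 2 * batch)
    v1 <- lapply(seq_len(batch), function(i)
      pair_to_input(augment_pair(pairs[[idx[i]]], policy, seeds[2 * i - 1])))
    v2 <- lapply(seq_len(batch), function(i)
      pair_to_input(augment_pair(pairs[[idx[i]]], policy, seeds[2 * i])))
    f1 <- explore_forward(model, v1, training = TRUE)
    model <- f1$model
    f2 <- explore_forward(model, v2, training = TRUE)
    model <- f2$model
    loss <- 0
    gy1 <- matrix(0, batch, cfg$embed_dim)
    gy2 <- matrix(0, batch, cfg$embed_dim)
    for (i in seq_len(batch)) {
      loss <- loss + symmetrized_loss(f1$y[i, ], f2$z[i, ],
                                      f2$y[i, ], f1$z[i, ])
      g <- symmetrized_loss_grads(f1$y[i, ], f2$z[i, ],
                                  f2$y[i, ], f1$z[i, ])
      gy1[i, ] <- g$gy1
      gy2[i, ] <- g$gy2
    }
    loss <- loss / batch
    g1 <- explore_backward(model, f1$caches, gy1 / batch)
    g2 <- explore_backward(model, f2$caches, gy2 / batch)
    grads <- tree_add(g1, g2)
    upd <- sgd_step(model$params[param_names_explore(model$params)],
                    grads[param_names_explore(model$params)],
                    state, lr, cfg$momentum, cfg$weight_decay)
    model$params[param_names_explore(model$params)] <- upd$params
    state <- upd$state
    model$loss_history <- c(model$loss_history, loss)
  }
  model
}

# BN running stats are not optimizer state; only true parameters get updates
param_names_explore <- function(params) names(params)

#' Embed a dataset of patch pairs
#'
#' Evaluation-mode forward pass (batch-norm running statistics, no
#' augmentation). One record per pair, order preserved.
#'
#' @param model a trained `exploration_model`.
#' @param pairs list of `patch_pair`s with the training patch size.
#' @return list with matrices `z` (projector outputs, n x 128), `y`
#'   (predictor outputs) and `coords` (n x 3).
#' @export
embed_dataset <- function(model, pairs) {
  if (length(pairs) == 0) stop("empty dataset")
  sides <- vapply(pairs, `[[`, integer(1), "side")
  expected <- nrow(pair_to_input(pairs[[1]]))
  if (any(sides != sides[1]))
    stop("patch size mismatch within the dataset")
  inputs <- lapply(pairs, pair_to_input)
  # the projector-output normalization uses the statistics of the evaluated
  # dataset itself (single-pass), which keeps the embedding centered even
  # after very short training runs
  fw <- explore_forward(model, inputs, training = FALSE,
                        bn3_batch = length(pairs) > 1)
  coords <- do.call(rbind, lapply(pairs, `[[`, "coord"))
  list(z = fw$z, y = fw$y, coords = coords)
}
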