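#' Train the few-shot voxel-level particle detector
#'
#' Optimizes the combined objective
#' risk + lambda1 (L_sup + lambda2 L_unsup) + lambda3 L_cons
#' over random subvolume crops (default 64 x 64 x 5, batch 2) with the Adam
#' optimizer, decaying the learning rate by `lr_decay_factor` every
#' `lr_decay_every` epochs. Each crop is paired with a spatially transformed
#' view (flips / 90-degree rotations, which have exact inverses); the
#' augmented prediction and feature map are re-aligned to the reference
#' frame before the consistency and contrastive terms. The positive-class
#' prior defaults to the expected particle volume fraction
#' (expected_particles x expected_radius ball / volume size) when
#' `cfg$pi_p` is `NA`. Preprocessing (wedge-subspace projection, Gaussian
#' denoising, intensity rescaling) is applied internally and remembered by
#' the model. Deterministic given `cfg$seed`.
#'
#' Ablations: `cfg$ablate_contrastive` drops the contrastive and consistency
#' terms (lambda1 = lambda3 = 0); `cfg$ablate_pu` replaces the
#' positive-unlabeled risk by a plain focal loss that treats unlabeled
#' voxels as negatives.
#'
#' @param vol a [tomogram_volume()] or 3D array (raw; preprocessing is
#'   applied internally and remembered by the model).
#' @param coords a [coord_table()] of annotated particle centers.
#' @param cfg a [default_config()]-style configuration.
#' @return a trained `detector_model` with `loss_history`.
#' @export
train_detector <- function(vol, coords, cfg = default_config()) {
  if (nrow(coords) == 0) stop("empty annotation table")
  v_raw <- as_volume_array(vol)
  d <- dim(v_raw)
  validate_coords(coords, d)
  model <- init_detector(cfg)
  v <- detector_preprocess(model, v_raw)
  cfg <- model$cfg
  if (is.na(cfg$pi_p)) {
    # positive-class prior: expected particle volume fraction
    cfg$pi_p <- min(0.5, cfg$expected_particles * (4 / 3) * pi *
                      cfg$expected_radius^3 / prod(d))
    model$cfg$pi_p <- cfg$pi_p
  }
  target <- make_target_heatmap(coords, d, cfg$mode, cfg$sigma_k,
                                cfg$tube_label_radius)
  Yfull <- target$Y

  cw <- min(cfg$crop_xy, d[1]); ch <- min(cfg$crop_xy, d[2])
  bl <- 2^cfg$unet_blocks
  cw <- (cw %/% bl) * bl; ch <- (ch %/% bl) * bl
  cz <- min(cfg$crop_z, d[3])

  set.seed(cfg$seed + 1L)
  state <- adam_make(model$params)
  n_ann <- nrow(coords)
  for (epoch in seq_len(cfg$detect_epochs)) {
    lr <- cfg$detect_lr / cfg$lr_decay_factor^((epoch - 1) %/%
                                                 cfg$lr_decay_every)
    for (step in seq_len(cfg$steps_per_epoch)) {
      grads <- NULL
      loss_acc <- 0
      for (bi in seq_len(cfg$detect_batch)) {
        # crop around a random annotation so >= 1 true-positive voxel exists
        a <- sample.int(n_ann, 1)
        x0 <- crop_origin(coords$x[a], cw, d[1])
        y0 <- crop_origin(coords$y[a], ch, d[2])
        z0 <- crop_origin(coords$z[a], cz, d[3])
        X <- v[x0 + seq_len(cw), y0 + seq_len(ch), z0 + seq_len(cz)]
        Yc <- Yfull[x0 + seq_len(cw), y0 + seq_len(ch), z0 + seq_len(cz)]
        if (!any(Yc == 1)) next
        res <- detector_step(model, X, Yc, cfg)
        loss_acc <- loss_acc + res$loss
        grads <- if (is.null(grads)) res$grads else tree_add(grads, res$grads)
      }
      if (is.null(grads)) next
      grads <- tree_scale(grads, 1 / cfg$detect_batch)
      upd <- adam_step(model$params, grads, state, lr)
      model$params <- upd$params
      state <- upd$state
      model$loss_history <- c(model$loss_history,
                              loss_acc / cfg$detect_batch)
    }
  }
  model
}

crop_origin <- function(center, size, dim_len) {
  if (size >= dim_len) return(0L)
  lo <- max(0L, ceiling(center) - size + 1L)
  hi <- min(dim_len - size, floor(center))
  if (hi < lo) hi <- lo
  lo + sample.int(hi - lo + 1L, 1) - 1L
}

# one training example: forward both views, assemble the loss and its
# gradient, backprop through both (shared-weight) branches
detector_step <- function(model, X, Yc, cfg) {
  use_contrast <- !cfg$ablate_contrastive
  # 90-degree rotations need a square xy crop; otherwise flips/180 only
  k <- if (dim(X)[1] == dim(X)[2]) sample(0:3, 1) else sample(c(0L, 2L), 1)
  flip <- runif(1) < 0.5
  X2 <- d4_apply(X, k, flip)
  f1 <- detector_forward(model, X)
  f2 <- detector_forward(model, X2)
  yhat2a <- d4_invert(f2$yhat, k, flip)

  risk_impl <- if (cfg$ablate_pu) focal_risk_pn_impl else pu_focal_risk_impl
  r1 <- risk_impl(f1$yhat, Yc, cfg, want_grad = TRUE)
  r2 <- risk_impl(yhat2a, Yc, cfg, want_grad = TRUE)
  risk <- 0.5 * (r1$risk + r2$risk)
  g_yhat1 <- 0.5 * r1$grad
  g_yhat2a <- 0.5 * r2$grad

  l_cons <- 0
  if (use_contrast && cfg$lambda3 > 0) {
    l_cons <- consistency_mse(f1$yhat, yhat2a)
    n <- length(f1$yhat)
    g_yhat1 <- g_yhat1 + cfg$lambda3 * 2 * (f1$yhat - yhat2a) / n
    g_yhat2a <- g_yhat2a - cfg$lambda3 * 2 * (f1$yhat - yhat2a) / n
  }

  l_sup <- 0; l_unsup <- 0
  gF1 <- NULL; gF2a <- NULL
  if (use_contrast && cfg$lambda1 > 0) {
    F2a <- d4_invert4(f2$F, k, flip)
    idx_p <- which(Yc == 1)
    idx_u <- which(Yc < 1)
    if (length(idx_u) > cfg$contrast_subsample)
      idx_u <- sort(sample(idx_u, cfg$contrast_subsample))
    M1 <- flatten_features(f1$F); M2 <- flatten_features(F2a)
    Ch <- ncol(M1)
    sup <- sup_contrastive_impl(rbind(M1[idx_p, , drop = FALSE],
                                      M2[idx_p, , drop = FALSE]),
                                rbind(M1[idx_u, , drop = FALSE],
                                      M2[idx_u, , drop = FALSE]),
                                cfg$pi_p, cfg$temperature, want_grad = TRUE)
    uns <- unsup_contrastive_impl(M1[idx_u, , drop = FALSE],
                                  M2[idx_u, , drop = FALSE],
                                  M1[idx_p, , drop = FALSE],
                                  M2[idx_p, , drop = FALSE],
                                  as.numeric(f1$yhat)[idx_u],
                                  cfg$pi_p, cfg$temperature,
                                  c(cfg$pseudo_pos_threshold,
                                    cfg$pseudo_neg_threshold),
                                  want_grad = TRUE)
    l_sup <- sup$loss; l_unsup <- uns$loss
    np <- length(idx_p); nu <- length(idx_u)
    G1 <- matrix(0, nrow(M1), Ch); G2 <- matrix(0, nrow(M2), Ch)
    w1 <- cfg$lambda1
    w2 <- cfg$lambda1 * cfg$lambda2
    if (!is.null(sup$gFp)) {
      G1[idx_p, ] <- G1[idx_p, ] + w1 * sup$gFp[seq_len(np), , drop = FALSE]
      G2[idx_p, ] <- G2[idx_p, ] + w1 * sup$gFp[np + seq_len(np), ,
                                                drop = FALSE]
      G1[idx_u, ] <- G1[idx_u, ] + w1 * sup$gFu[seq_len(nu), , drop = FALSE]
      G2[idx_u, ] <- G2[idx_u, ] + w1 * sup$gFu[nu + seq_len(nu), ,
                                                drop = FALSE]
    }
    if (!is.null(uns$gU1)) {
      G1[idx_u, ] <- G1[idx_u, ] + w2 * uns$gU1
      G2[idx_u, ] <- G2[idx_u, ] + w2 * uns$gU2
      if (np > 0) {
        G1[idx_p, ] <- G1[idx_p, ] + w2 * uns$gP1
        G2[idx_p, ] <- G2[idx_p, ] + w2 * uns$gP2
      }
    }
    dF <- dim(f1$F)
    gF1 <- array(G1, dim = dF)
    gF2a <- array(G2, dim = dF)
  }

  loss <- total_loss(risk, l_sup, l_unsup, l_cons, cfg)
  # chain d/dyhat -> d/dlogit, re-transform view-2 gradients, backprop
  gl1 <- g_yhat1 * f1$yhat * (1 - f1$yhat)
  gl2a <- g_yhat2a * yhat2a * (1 - yhat2a)
  gl2 <- d4_apply(gl2a, k, flip)
  g2F <- if (is.null(gF2a)) NULL else d4_apply4(gF2a, k, flip)
  g1 <- detector_backward(model, f1$caches, gl1, gF1)
  g2 <- detector_backward(model, f2$caches, gl2, g2F)
  list(loss = loss, grads = tree_add(g1, g2))
}
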