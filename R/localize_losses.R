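# Detector losses: non-negative positive-unlabeled focal risk, debiased
# supervised / self-supervised contrastive regularization, consistency MSE,
# and their analytic gradients (verified against finite differences in the
# test suite).
#
# Sign convention: the per-voxel focal expressions are log-likelihood style
# (negative-valued); risks are their negatives, so minimization is well posed
# and a perfect classifier drives the risk to 0.

EPS_PROB <- 1e-6

clamp_prob <- function(p) pmin(pmax(p, EPS_PROB), 1 - EPS_PROB)

split_target_groups <- function(Y) {
  list(tp = which(Y == 1), sp = which(Y > 0 & Y < 1), u = which(Y < 0))
}

check_priors <- function(pi_p) {
  if (is.na(pi_p) || pi_p <= 0 || pi_p >= 1)
    stop("invalid class prior pi_p; need 0 < pi_p < 1")
}

#' Non-negative positive-unlabeled focal risk
#'
#' Voxel-level PU risk with focal weighting for a predicted heat map Yhat in
#' \[0,1\] against a target Y whose voxels are true positives (Y = 1), soft
#' positives (0 < Y < 1, Gaussian shoulders) or unlabeled (Y = -1):
#' \deqn{R = \pi_p(\pi_{tp} R^+_{tp} + \pi_{sp} R^+_{sp}) +
#'   \max\{0, R^-_u - \pi_p(\pi_{tp} R^-_{tp} + \pi_{sp} R^-_{sp})\}}
#' where each R term is the mean over its voxel group of the focal negative
#' log-likelihood (exponents `alpha` on the prediction, `beta` on the soft
#' label). pi_tp is taken from the target group sizes; with no soft
#' positives (tubular targets) the sp terms vanish and the plain
#' non-negative PU form remains.
#'
#' @param yhat predicted heat map (array or vector), values in \[0, 1\].
#' @param Y target heat map of the same shape (a `target_heatmap` or array).
#' @param cfg configuration carrying `alpha`, `beta`, `pi_p` and `pi_tp`
#'   (`NA` falls back to the voxel-count ratio n_tp / (n_tp + n_sp)).
#' @return scalar risk (non-negative).
#' @export
pu_focal_risk <- function(yhat, Y, cfg = default_config()) {
  pu_focal_risk_impl(yhat, Y, cfg, want_grad = FALSE)$risk
}

pu_focal_risk_impl <- function(yhat, Y, cfg, want_grad = FALSE) {
  if (inherits(Y, "target_heatmap")) Y <- Y$Y
  if (!identical(length(yhat), length(Y))) stop("shape mismatch")
  check_priors(cfg$pi_p)
  g <- split_target_groups(Y)
  if (length(g$tp) == 0)
    stop("no positive (Y = 1) voxels: few-shot training requires >= 1 label")
  a <- cfg$alpha; b <- cfg$beta
  pi_p <- cfg$pi_p
  # mixture weight of centers vs shoulders within the positive class; the
  # voxel-count estimator collapses to ~0 for Gaussian targets (one center
  # voxel vs hundreds of shoulder voxels) and removes all center
  # supervision, so the default treats the two sub-groups as equal halves
  pi_tp <- if (is.na(cfg$pi_tp))
    length(g$tp) / (length(g$tp) + length(g$sp)) else cfg$pi_tp
  if (length(g$sp) == 0) pi_tp <- 1   # tubular targets: no soft positives
  pi_sp <- 1 - pi_tp
  p <- clamp_prob(yhat)

  ptp <- p[g$tp]; psp <- p[g$sp]; pu <- p[g$u]
  ysp <- Y[g$sp]
  m0 <- function(x) if (length(x)) mean(x) else 0
  r_tp_pos <- m0(-(1 - ptp)^a * log(ptp))
  r_sp_pos <- m0(-(1 - ysp)^b * psp^a * log(1 - psp))
  r_tp_neg <- m0(-ptp^a * log(1 - ptp))
  r_sp_neg <- m0(-ysp^b * (1 - psp)^a * log(psp))
  r_u_neg  <- m0(-pu^a * log(1 - pu))
  inner <- r_u_neg - pi_p * (pi_tp * r_tp_neg + pi_sp * r_sp_neg)
  risk <- pi_p * (pi_tp * r_tp_pos + pi_sp * r_sp_pos) + max(0, inner)
  if (!want_grad) return(list(risk = risk))

  active <- inner > 0
  grad <- array(0, dim = if (is.null(dim(yhat))) length(yhat) else dim(yhat))
  d_pos_like <- function(pp) a * pp^(a - 1) * log(1 - pp) - pp^a / (1 - pp)
  if (length(g$tp)) {
    d1 <- a * (1 - ptp)^(a - 1) * log(ptp) - (1 - ptp)^a / ptp  # d r_tp_pos
    d2 <- -d_pos_like(ptp)                                      # d r_tp_neg
    grad[g$tp] <- (pi_p * pi_tp / length(g$tp)) * d1 -
      (if (active) (pi_p * pi_tp / length(g$tp)) * d2 else 0)
  }
  if (length(g$sp)) {
    d1 <- -(1 - ysp)^b * (a * psp^(a - 1) * log(1 - psp) - psp^a / (1 - psp))
    d2 <- ysp^b * (a * (1 - psp)^(a - 1) * log(psp) - (1 - psp)^a / psp)
    grad[g$sp] <- (pi_p * pi_sp / length(g$sp)) * d1 -
      (if (active) (pi_p * pi_sp / length(g$sp)) * d2 else 0)
  }
  if (length(g$u) && active) {
    grad[g$u] <- (1 / length(g$u)) * (-d_pos_like(pu))
  }
  grad[yhat < EPS_PROB | yhat > 1 - EPS_PROB] <- 0  # clamped region
  list(risk = risk, grad = grad)
}

#' Plain focal risk treating unlabeled voxels as negatives
#'
#' The PU-ablated objective: true positives keep the focal positive term;
#' every other voxel is treated as a negative with shoulder down-weighting
#' (1 - max(Y, 0))^beta.
#'
#' @inheritParams pu_focal_risk
#' @return scalar risk.
#' @export
focal_risk_pn <- function(yhat, Y, cfg = default_config()) {
  focal_risk_pn_impl(yhat, Y, cfg, want_grad = FALSE)$risk
}

focal_risk_pn_impl <- function(yhat, Y, cfg, want_grad = FALSE) {
  if (inherits(Y, "target_heatmap")) Y <- Y$Y
  g <- split_target_groups(Y)
  if (length(g$tp) == 0)
    stop("no positive (Y = 1) voxels: few-shot training requires >= 1 label")
  a <- cfg$alpha; b <- cfg$beta
  p <- clamp_prob(yhat)
  neg_idx <- c(g$sp, g$u)
  w <- (1 - pmax(Y[neg_idx], 0))^b
  ptp <- p[g$tp]; pn <- p[neg_idx]
  risk <- mean(-(1 - ptp)^a * log(ptp)) + mean(-w * pn^a * log(1 - pn))
  if (!want_grad) return(list(risk = risk))
  grad <- array(0, dim = if (is.null(dim(yhat))) length(yhat) else dim(yhat))
  grad[g$tp] <- (a * (1 - ptp)^(a - 1) * log(ptp) - (1 - ptp)^a / ptp) /
    length(g$tp)
  grad[neg_idx] <- -w * (a * pn^(a - 1) * log(1 - pn) - pn^a / (1 - pn)) /
    length(neg_idx)
  grad[yhat < EPS_PROB | yhat > 1 - EPS_PROB] <- 0
  list(risk = risk, grad = grad)
}

# ---------------------------------------------------------------------------
# contrastive losses

l2_normalize_rows <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  if (any(nrm == 0)) stop("zero feature vector cannot be normalized")
  M / nrm
}

# chain a gradient w.r.t. normalized rows back to the raw rows
denormalize_grad <- function(G_hat, M_raw, M_hat) {
  nrm <- sqrt(rowSums(M_raw^2))
  (G_hat - M_hat * rowSums(G_hat * M_hat)) / nrm
}

#' Debiased supervised contrastive loss on positive/unlabeled feature sets
#'
#' Core computation on feature matrices. Rows are L2-normalized; pair
#' similarities are exp(f_i . f_j / t). For each positive anchor the other
#' 2 n_p - 1 positive vectors (across both views) are positives and all
#' unlabeled vectors are negatives; the negative mass in the denominator is
#' the debiased estimator
#' g_sup = max\{ (mean_u - pi_p * mean_p) / pi_n, exp(-1/t) \}.
#'
#' @param Fp matrix (2 n_p x Ch) of positive feature vectors, both views
#'   stacked.
#' @param Fu matrix (2 n_n x Ch) of unlabeled feature vectors, both views.
#' @param pi_p positive class prior in (0, 1).
#' @param t temperature, > 0.
#' @return scalar loss (mean over positive anchors).
#' @export
sup_contrastive_core <- function(Fp, Fu, pi_p, t) {
  sup_contrastive_impl(Fp, Fu, pi_p, t, want_grad = FALSE)$loss
}

sup_contrastive_impl <- function(Fp, Fu, pi_p, t, want_grad = FALSE) {
  check_priors(pi_p)
  m <- nrow(Fp)
  if (m < 2) {
    warning("fewer than 2 positive feature vectors; contrastive loss is 0")
    return(list(loss = 0,
                gFp = matrix(0, nrow(Fp), ncol(Fp)),
                gFu = matrix(0, nrow(Fu), ncol(Fu))))
  }
  pi_n <- 1 - pi_p
  P <- l2_normalize_rows(Fp)
  U <- l2_normalize_rows(Fu)
  S <- exp(P %*% t(P) / t); diag(S) <- 0
  Tm <- exp(P %*% t(U) / t)
  A <- rowSums(S) / (m - 1)
  B <- if (nrow(U) > 0) rowSums(Tm) / nrow(U) else rep(0, m)
  gso <- (B - pi_p * A) / pi_n
  floor_g <- exp(-1 / t)
  gs <- pmax(gso, floor_g)
  L <- mean(log(A + gs) - log(A))
  if (!want_grad) return(list(loss = L))

  act <- as.numeric(gso > floor_g)
  dA <- (1 / (A + gs) - 1 / A + act * (-pi_p / pi_n) / (A + gs)) / m
  dB <- (act / pi_n / (A + gs)) / m
  # dL/dS_ij and dL/dT_ik, then pair-gradient G = (C + C^t) V with
  # C = dL/dE * E / t for each similarity block
  Cs <- (dA / (m - 1)) * S / t          # recycles dA over rows
  Ct <- (dB / nrow(U)) * Tm / t
  Gp_hat <- (Cs + t(Cs)) %*% P + Ct %*% U
  Gu_hat <- t(Ct) %*% P
  list(loss = L,
       gFp = denormalize_grad(Gp_hat, Fp, P),
       gFu = denormalize_grad(Gu_hat, Fu, U))
}

#' Debiased supervised contrastive loss from feature maps
#'
#' Wrapper over [sup_contrastive_core()]: positive vectors are taken at
#' voxels with Y = 1 in both the reference feature map and its (re-aligned)
#' augmented counterpart; unlabeled vectors (Y < 1) are the negatives.
#'
#' @param F_map,F_aug arrays (W, H, D, Ch): projected feature maps of the
#'   two views, spatially aligned.
#' @param Y target heat map (`target_heatmap` or array).
#' @param cfg configuration carrying `pi_p` and `temperature`.
#' @param max_unlabeled optional cap on unlabeled vectors (deterministic
#'   subsample under the current RNG state).
#' @return scalar loss.
#' @export
sup_debiased_contrastive <- function(F_map, F_aug, Y, cfg = default_config(),
                                     max_unlabeled = NULL) {
  if (inherits(Y, "target_heatmap")) Y <- Y$Y
  idx_p <- which(Y == 1)
  idx_u <- which(Y < 1)
  if (!is.null(max_unlabeled) && length(idx_u) > max_unlabeled)
    idx_u <- sort(sample(idx_u, max_unlabeled))
  Fp <- rbind(flatten_features(F_map)[idx_p, , drop = FALSE],
              flatten_features(F_aug)[idx_p, , drop = FALSE])
  Fu <- rbind(flatten_features(F_map)[idx_u, , drop = FALSE],
              flatten_features(F_aug)[idx_u, , drop = FALSE])
  sup_contrastive_core(Fp, Fu, cfg$pi_p, cfg$temperature)
}

flatten_features <- function(F_map) {
  d <- dim(F_map)
  matrix(F_map, prod(d[1:3]), d[4])
}

#' Debiased self-supervised contrastive loss for unlabeled vectors
#'
#' Core computation. Each unlabeled vector (in either view) is an anchor
#' whose only positive is its augmented twin; the remaining 2N - 2 vectors
#' (positives included) are negatives. The debiased negative mass uses the
#' negative-class prior for pseudo-positive anchors (predicted probability
#' > 0.9), the positive-class prior for pseudo-negatives (< 0.3), both
#' floored at exp(-1/t); neutral anchors take the prediction-weighted
#' average yhat * L^p + (1 - yhat) * L^n.
#'
#' @param U1,U2 matrices (n_u x Ch): unlabeled feature vectors of the two
#'   views, rows aligned (row k of U2 is the augmented twin of row k of U1).
#' @param P1,P2 matrices (n_p x Ch): positive feature vectors of the two
#'   views (may have zero rows).
#' @param yhat_u numeric (n_u): predicted particle probability at each
#'   unlabeled anchor voxel (reference frame; treated as constant).
#' @param pi_p positive class prior; `t` temperature.
#' @param t temperature.
#' @param thresholds pseudo-positive / pseudo-negative probability cutoffs.
#' @return scalar loss (mean over the 2 n_u anchors).
#' @export
unsup_contrastive_core <- function(U1, U2, P1, P2, yhat_u, pi_p, t,
                                   thresholds = c(0.9, 0.3)) {
  unsup_contrastive_impl(U1, U2, P1, P2, yhat_u, pi_p, t, thresholds,
                         want_grad = FALSE)$loss
}

unsup_contrastive_impl <- function(U1, U2, P1, P2, yhat_u, pi_p, t,
                                   thresholds = c(0.9, 0.3),
                                   want_grad = FALSE) {
  check_priors(pi_p)
  n_u <- nrow(U1)
  Ch <- ncol(U1)
  if (n_u == 0) return(list(loss = 0))
  pi_n <- 1 - pi_p
  V_raw <- rbind(P1, P2, U1, U2)
  V <- l2_normalize_rows(V_raw)
  n_p <- nrow(P1)
  N <- n_p + n_u
  i_u1 <- 2 * n_p + seq_len(n_u)
  i_u2 <- 2 * n_p + n_u + seq_len(n_u)
  E <- exp(V %*% t(V) / t)
  rs <- rowSums(E)
  floor_g <- exp(-1 / t)
  w <- ifelse(yhat_u > thresholds[1], 1,
              ifelse(yhat_u < thresholds[2], 0, yhat_u))

  dE <- if (want_grad) matrix(0, 2 * N, 2 * N) else NULL
  total <- 0
  n_anchor <- 2 * n_u
  for (side in 1:2) {
    ia <- if (side == 1) i_u1 else i_u2
    ib <- if (side == 1) i_u2 else i_u1
    for (k in seq_len(n_u)) {
      a <- ia[k]; bb <- ib[k]
      e <- E[a, bb]
      mS <- (rs[a] - E[a, a] - e) / (2 * N - 2)
      gp_o <- (mS - pi_n * e) / pi_n
      gn_o <- (mS - pi_p * e) / pi_p
      gp <- max(gp_o, floor_g); gn <- max(gn_o, floor_g)
      Lp <- log(e + gp) - log(e)
      Ln <- log(e + gn) - log(e)
      total <- total + w[k] * Lp + (1 - w[k]) * Ln
      if (want_grad) {
        ap <- as.numeric(gp_o > floor_g); an <- as.numeric(gn_o > floor_g)
        dLp_de <- (1 - ap) / (e + gp) - 1 / e
        dLp_dm <- ap / (pi_n * (e + gp))
        dLn_de <- (1 - an) / (e + gn) - 1 / e
        dLn_dm <- an / (pi_p * (e + gn))
        de <- (w[k] * dLp_de + (1 - w[k]) * dLn_de) / n_anchor
        dm <- (w[k] * dLp_dm + (1 - w[k]) * dLn_dm) / n_anchor
        dE[a, ] <- dE[a, ] + dm / (2 * N - 2)
        dE[a, a] <- dE[a, a] - dm / (2 * N - 2)
        dE[a, bb] <- dE[a, bb] - dm / (2 * N - 2) + de
      }
    }
  }
  L <- total / n_anchor
  if (!want_grad) return(list(loss = L))
  C <- dE * E / t
  G_hat <- (C + t(C)) %*% V
  G <- denormalize_grad(G_hat, V_raw, V)
  list(loss = L,
       gP1 = G[seq_len(n_p), , drop = FALSE],
       gP2 = G[n_p + seq_len(n_p), , drop = FALSE],
       gU1 = G[i_u1, , drop = FALSE],
       gU2 = G[i_u2, , drop = FALSE])
}

#' Debiased self-supervised contrastive loss from feature maps
#'
#' Wrapper over [unsup_contrastive_core()] taking spatially aligned feature
#' maps, the target (to separate positive from unlabeled voxels) and the
#' predicted heat map (for the pseudo-group weighting).
#'
#' @inheritParams sup_debiased_contrastive
#' @param yhat predicted heat map in the reference frame.
#' @param Y target heat map.
#' @param max_unlabeled optional cap on unlabeled anchors.
#' @return scalar loss.
#' @export
unsup_debiased_contrastive <- function(F_map, F_aug, yhat, Y,
                                       cfg = default_config(),
                                       max_unlabeled = NULL) {
  if (inherits(Y, "target_heatmap")) Y <- Y$Y
  idx_p <- which(Y == 1)
  idx_u <- which(Y < 1)
  if (!is.null(max_unlabeled) && length(idx_u) > max_unlabeled)
    idx_u <- sort(sample(idx_u, max_unlabeled))
  M1 <- flatten_features(F_map); M2 <- flatten_features(F_aug)
  unsup_contrastive_core(M1[idx_u, , drop = FALSE], M2[idx_u, , drop = FALSE],
                         M1[idx_p, , drop = FALSE], M2[idx_p, , drop = FALSE],
                         as.numeric(yhat)[idx_u], cfg$pi_p, cfg$temperature,
                         c(cfg$pseudo_pos_threshold, cfg$pseudo_neg_threshold))
}

#' Consistency loss between a heat map and its re-aligned augmented twin
#'
#' @param yhat,yhat_aug arrays of identical shape (the augmented map must be
#'   mapped back to the reference frame first).
#' @return mean squared difference.
#' @export
consistency_mse <- function(yhat, yhat_aug) {
  if (!identical(dim(yhat), dim(yhat_aug)) ||
      length(yhat) != length(yhat_aug))
    stop("shape mismatch between heat maps")
  mean((yhat - yhat_aug)^2)
}

#' Total detector training objective
#'
#' risk + lambda1 (L_sup + lambda2 L_unsup) + lambda3 L_cons with defaults
#' lambda1 = 0.1, lambda2 = 0.5, lambda3 = 0.1.
#'
#' @param risk PU focal risk value.
#' @param l_sup,l_unsup,l_cons contrastive and consistency components.
#' @param cfg configuration carrying lambda1..lambda3.
#' @return scalar objective.
#' @export
total_loss <- function(risk, l_sup, l_unsup, l_cons, cfg = default_config()) {
  risk + cfg$lambda1 * (l_sup + cfg$lambda2 * l_unsup) + cfg$lambda3 * l_cons
}
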