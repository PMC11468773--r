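# Independent brute-force oracles, coded directly from the written formulas
# with naive loops. They share no code with the package implementations.

# greedy NMS oracle: O(n^2) scan over voxels sorted by value
oracle_nms <- function(resp, radius, threshold, max_candidates = .Machine$integer.max) {
  d <- dim(resp)
  rows <- NULL
  for (z in 0:(d[3] - 1))
    for (y in 0:(d[2] - 1))
      for (x in 0:(d[1] - 1)) {
        v <- resp[x + 1, y + 1, z + 1]
        if (v > threshold) rows <- rbind(rows, c(x, y, z, v))
      }
  if (is.null(rows)) return(matrix(0, 0, 4))
  ord <- order(-rows[, 4], rows[, 1], rows[, 2], rows[, 3])
  rows <- rows[ord, , drop = FALSE]
  kept <- matrix(0, 0, 4)
  for (i in seq_len(nrow(rows))) {
    if (nrow(kept) >= max_candidates) break
    ok <- TRUE
    for (j in seq_len(nrow(kept))) {
      if (sum((rows[i, 1:3] - kept[j, 1:3])^2) <= radius^2) { ok <- FALSE; break }
    }
    if (ok) kept <- rbind(kept, rows[i, ])
  }
  kept
}

# local-maximum extraction oracle with the same lexicographic tie rule
oracle_local_max <- function(heat, kernel, threshold) {
  d <- dim(heat)
  h <- kernel %/% 2
  kept <- NULL
  for (z in 0:(d[3] - 1))
    for (y in 0:(d[2] - 1))
      for (x in 0:(d[1] - 1)) {
        v <- heat[x + 1, y + 1, z + 1]
        if (v <= threshold) next
        keep <- TRUE
        for (dz in -h:h) for (dy in -h:h) for (dx in -h:h) {
          xx <- x + dx; yy <- y + dy; zz <- z + dz
          if (xx < 0 || yy < 0 || zz < 0 ||
              xx >= d[1] || yy >= d[2] || zz >= d[3]) next
          if (dx == 0 && dy == 0 && dz == 0) next
          u <- heat[xx + 1, yy + 1, zz + 1]
          if (u > v) keep <- FALSE
          if (u == v) {
            v_first <- x < xx || (x == xx && (y < yy || (y == yy && z < zz)))
            if (!v_first) keep <- FALSE
          }
        }
        if (keep) kept <- rbind(kept, c(x, y, z, v))
      }
  if (is.null(kept)) matrix(0, 0, 4) else kept
}

# greedy score-ordered matching oracle
oracle_greedy_match <- function(pred, gt, radius) {
  ord <- if (all(is.na(pred$score))) seq_len(nrow(pred))
         else order(pred$score, decreasing = TRUE)
  used <- rep(FALSE, nrow(gt))
  flags <- integer(nrow(pred))
  for (i in seq_along(ord)) {
    p <- pred[ord[i], ]
    best <- Inf; bj <- 0
    for (j in seq_len(nrow(gt))) {
      if (used[j]) next
      dd <- sqrt((gt$x[j] - p$x)^2 + (gt$y[j] - p$y)^2 + (gt$z[j] - p$z)^2)
      if (dd < best) { best <- dd; bj <- j }
    }
    if (bj > 0 && best <= radius) { flags[i] <- 1L; used[bj] <- TRUE }
  }
  flags
}

# union-find connected components oracle for distance grouping
oracle_groups <- function(coords, cutoff) {
  n <- nrow(coords)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      dd <- sqrt((coords$x[i] - coords$x[j])^2 +
                 (coords$y[i] - coords$y[j])^2 +
                 (coords$z[i] - coords$z[j])^2)
      if (dd <= cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  grp <- split(seq_len(n), roots)
  grp <- lapply(grp, sort)
  unname(grp[order(vapply(grp, min, integer(1)))])
}

# per-voxel PU focal risk oracle: direct transcription of the risk
# decomposition, looping voxel by voxel
oracle_pu_risk <- function(yhat, Y, alpha, beta, pi_p, pi_tp) {
  eps <- 1e-6
  p <- pmin(pmax(yhat, eps), 1 - eps)
  tp <- sp <- u <- c()
  for (i in seq_along(Y)) {
    if (Y[i] == 1) tp <- c(tp, i)
    else if (Y[i] > 0 && Y[i] < 1) sp <- c(sp, i)
    else u <- c(u, i)
  }
  if (length(sp) == 0) pi_tp <- 1
  pi_sp <- 1 - pi_tp
  msum <- function(idx, f) if (length(idx) == 0) 0 else {
    tot <- 0
    for (i in idx) tot <- tot + f(p[i], Y[i])
    tot / length(idx)
  }
  r_tp_pos <- msum(tp, function(ph, yv) -(1 - ph)^alpha * log(ph))
  r_sp_pos <- msum(sp, function(ph, yv) -(1 - yv)^beta * ph^alpha * log(1 - ph))
  r_tp_neg <- msum(tp, function(ph, yv) -ph^alpha * log(1 - ph))
  r_sp_neg <- msum(sp, function(ph, yv) -yv^beta * (1 - ph)^alpha * log(ph))
  r_u_neg <- msum(u, function(ph, yv) -ph^alpha * log(1 - ph))
  pi_p * (pi_tp * r_tp_pos + pi_sp * r_sp_pos) +
    max(0, r_u_neg - pi_p * (pi_tp * r_tp_neg + pi_sp * r_sp_neg))
}

# supervised debiased contrastive oracle: double loop over anchors/partners
oracle_sup_contrastive <- function(Fp, Fu, pi_p, t) {
  nrm <- function(v) v / sqrt(sum(v^2))
  P <- t(apply(Fp, 1, nrm)); U <- if (nrow(Fu)) t(apply(Fu, 1, nrm)) else Fu
  m <- nrow(P)
  total <- 0
  for (i in seq_len(m)) {
    num <- 0
    for (j in seq_len(m)) if (j != i)
      num <- num + exp(sum(P[i, ] * P[j, ]) / t)
    num <- num / (m - 1)
    den_u <- 0
    for (k in seq_len(nrow(U)))
      den_u <- den_u + exp(sum(P[i, ] * U[k, ]) / t)
    den_u <- if (nrow(U)) den_u / nrow(U) else 0
    g <- max((den_u - pi_p * num) / (1 - pi_p), exp(-1 / t))
    total <- total - log(num / (num + g))
  }
  total / m
}

# unsupervised debiased contrastive oracle
oracle_unsup_contrastive <- function(U1, U2, P1, P2, yhat_u, pi_p, t,
                                     thr = c(0.9, 0.3)) {
  nrm <- function(v) v / sqrt(sum(v^2))
  V <- rbind(P1, P2, U1, U2)
  V <- t(apply(V, 1, nrm))
  n_p <- nrow(P1); n_u <- nrow(U1); N <- n_p + n_u
  total <- 0
  for (side in 1:2) for (k in seq_len(n_u)) {
    a <- 2 * n_p + (side - 1) * n_u + k
    b <- 2 * n_p + (2 - side) * n_u + k
    e <- exp(sum(V[a, ] * V[b, ]) / t)
    mS <- 0
    for (l in seq_len(2 * N)) if (l != a && l != b)
      mS <- mS + exp(sum(V[a, ] * V[l, ]) / t)
    mS <- mS / (2 * N - 2)
    gp <- max((mS - (1 - pi_p) * e) / (1 - pi_p), exp(-1 / t))
    gn <- max((mS - pi_p * e) / pi_p, exp(-1 / t))
    Lp <- -log(e / (e + gp)); Ln <- -log(e / (e + gn))
    w <- if (yhat_u[k] > thr[1]) 1 else if (yhat_u[k] < thr[2]) 0 else yhat_u[k]
    total <- total + w * Lp + (1 - w) * Ln
  }
  total / (2 * n_u)
}
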