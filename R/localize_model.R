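# Few-shot voxel-level particle detector: a per-slice 2D UNet feature
# extractor, one 3D fusion convolution (3x3x3) and two 1x1x1 heads — a
# sigmoid center head producing the predicted heat map and a linear
# projection head producing the contrastive feature map. Output stride is 1.

init_detector <- function(cfg = default_config()) {
  set.seed(cfg$seed)
  B <- cfg$unet_blocks
  c0 <- cfg$unet_channels
  ch <- c0 * 2^(0:(B))     # encoder channels per level; bottleneck = ch[B+1]
  enc <- list()
  cin <- 2L * cfg$slice_context + 1L   # each slice sees a local z slab
  for (b in seq_len(B)) {
    enc[[b]] <- list(c1 = conv2d_make(3L, cin, ch[b]),
                     c2 = conv2d_make(3L, ch[b], ch[b]))
    cin <- ch[b]
  }
  bott <- list(c1 = conv2d_make(3L, ch[B], ch[B + 1]),
               c2 = conv2d_make(3L, ch[B + 1], ch[B + 1]))
  dec <- list()
  for (b in rev(seq_len(B))) {
    dec[[b]] <- list(up = tconv2_make(ch[b + 1], ch[b]),
                     c1 = conv2d_make(3L, 2L * ch[b], ch[b]),
                     c2 = conv2d_make(3L, ch[b], ch[b]))
  }
  params <- list(
    enc = enc, bott = bott, dec = dec,
    fusion = conv3d_make(c0, cfg$fusion_channels),
    center_w = he_init(c(cfg$fusion_channels, 1L), cfg$fusion_channels),
    center_b = -2.0,    # start with low particle probability everywhere
    feat_w = he_init(c(cfg$fusion_channels, cfg$contrast_channels),
                     cfg$fusion_channels),
    feat_b = numeric(cfg$contrast_channels))
  structure(list(params = params, cfg = cfg, loss_history = numeric(),
                 preprocess = list(denoise_sigma = cfg$denoise_sigma,
                                   bins = cfg$hist_bins,
                                   invert = cfg$invert_contrast,
                                   rescale = cfg$detect_rescale,
                                   wedge_filter = cfg$detect_wedge_filter)),
            class = "detector_model")
}

unet2d_fw <- function(params, x) {
  B <- length(params$enc)
  skips <- list()
  ca <- list(enc = vector("list", B), dec = vector("list", B))
  h <- x
  for (b in seq_len(B)) {
    p <- params$enc[[b]]
    a1 <- cpp_conv2d_fw(h, p$c1$w, p$c1$b); r1 <- relu_fw(a1)
    a2 <- cpp_conv2d_fw(r1$y, p$c2$w, p$c2$b); r2 <- relu_fw(a2)
    mp <- cpp_maxpool2_fw(r2$y)
    ca$enc[[b]] <- list(x = h, m1 = r1$mask, h1 = r1$y, m2 = r2$mask,
                        skip = r2$y, mp_idx = mp$idx, mp_dim = dim(r2$y))
    skips[[b]] <- r2$y
    h <- mp$y
  }
  p <- params$bott
  a1 <- cpp_conv2d_fw(h, p$c1$w, p$c1$b); r1 <- relu_fw(a1)
  a2 <- cpp_conv2d_fw(r1$y, p$c2$w, p$c2$b); r2 <- relu_fw(a2)
  ca$bott <- list(x = h, m1 = r1$mask, h1 = r1$y, m2 = r2$mask)
  h <- r2$y
  for (b in rev(seq_len(B))) {
    p <- params$dec[[b]]
    up <- cpp_tconv2_fw(h, p$up$w, p$up$b)
    cat_ <- abind3(up, skips[[b]])
    a1 <- cpp_conv2d_fw(cat_, p$c1$w, p$c1$b); r1 <- relu_fw(a1)
    a2 <- cpp_conv2d_fw(r1$y, p$c2$w, p$c2$b); r2 <- relu_fw(a2)
    ca$dec[[b]] <- list(upx = h, cat = cat_, m1 = r1$mask, h1 = r1$y,
                        m2 = r2$mask, nup = dim(up)[3])
    h <- r2$y
  }
  list(y = h, caches = ca)
}

abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

unet2d_bw <- function(params, ca, gy) {
  B <- length(params$enc)
  gr <- list(enc = vector("list", B), dec = vector("list", B))
  gskip <- vector("list", B)
  g <- gy
  for (b in seq_len(B)) {     # decoder blocks, innermost-last order reversed
    p <- params$dec[[b]]
    cc <- ca$dec[[b]]
    g2 <- relu_bw(cc$m2, g)
    bw2 <- cpp_conv2d_bw(cc$h1, p$c2$w, g2)
    g1 <- relu_bw(cc$m1, bw2$gx)
    bw1 <- cpp_conv2d_bw(cc$cat, p$c1$w, g1)
    nup <- cc$nup
    gup <- bw1$gx[, , seq_len(nup), drop = FALSE]
    gskip[[b]] <- bw1$gx[, , nup + seq_len(dim(bw1$gx)[3] - nup),
                         drop = FALSE]
    bwu <- cpp_tconv2_bw(cc$upx, p$up$w, gup)
    gr$dec[[b]] <- list(up = list(w = bwu$gw, b = bwu$gb),
                        c1 = list(w = bw1$gw, b = bw1$gb),
                        c2 = list(w = bw2$gw, b = bw2$gb))
    g <- bwu$gx
  }
  p <- params$bott
  cc <- ca$bott
  g2 <- relu_bw(cc$m2, g)
  bw2 <- cpp_conv2d_bw(cc$h1, p$c2$w, g2)
  g1 <- relu_bw(cc$m1, bw2$gx)
  bw1 <- cpp_conv2d_bw(cc$x, p$c1$w, g1)
  gr$bott <- list(c1 = list(w = bw1$gw, b = bw1$gb),
                  c2 = list(w = bw2$gw, b = bw2$gb))
  g <- bw1$gx
  for (b in rev(seq_len(B))) {
    p <- params$enc[[b]]
    cc <- ca$enc[[b]]
    g <- cpp_maxpool2_bw(cc$mp_idx, g, as.integer(cc$mp_dim))
    g <- g + gskip[[b]]
    g2 <- relu_bw(cc$m2, g)
    bw2 <- cpp_conv2d_bw(cc$h1, p$c2$w, g2)
    g1 <- relu_bw(cc$m1, bw2$gx)
    bw1 <- cpp_conv2d_bw(cc$x, p$c1$w, g1)
    gr$enc[[b]] <- list(c1 = list(w = bw1$gw, b = bw1$gb),
                        c2 = list(w = bw2$gw, b = bw2$gb))
    g <- bw1$gx
  }
  gr
}

detector_forward <- function(model, vol, want_caches = TRUE) {
  params <- model$params
  d <- dim(vol)
  if (d[3] < 3) stop("volume thinner than the 3D fusion receptive field")
  if (d[1] %% 2^model$cfg$unet_blocks != 0 ||
      d[2] %% 2^model$cfg$unet_blocks != 0)
    stop("x/y dimensions must be divisible by 2^unet_blocks")
  c0 <- model$cfg$unet_channels
  sctx <- model$cfg$slice_context
  if (is.null(sctx)) sctx <- 0L
  U <- array(0, dim = c(d[1], d[2], d[3], c0))
  slice_caches <- if (want_caches) vector("list", d[3]) else NULL
  for (z in seq_len(d[3])) {
    zz <- pmin(pmax(z + (-sctx):sctx, 1L), d[3])   # replicate at z edges
    sl <- vol[, , zz, drop = FALSE]
    fw <- unet2d_fw(params, sl)
    U[, , z, ] <- fw$y
    if (want_caches) slice_caches[[z]] <- fw$caches
  }
  A <- cpp_conv3d_fw(U, params$fusion$w, params$fusion$b)
  rmask <- A > 0
  M <- A * rmask
  nvox <- prod(d)
  Mf <- matrix(M, nvox, model$cfg$fusion_channels)
  logits <- array(Mf %*% params$center_w + params$center_b, dim = d)
  yhat <- sigmoid(logits)
  Fmap <- array(sweep(Mf %*% params$feat_w, 2, params$feat_b, "+"),
                dim = c(d, model$cfg$contrast_channels))
  list(yhat = yhat, logits = logits, F = Fmap,
       caches = if (want_caches)
         list(U = U, slices = slice_caches, rmask = rmask, Mf = Mf,
              dims = d) else NULL)
}

detector_backward <- function(model, caches, g_logits, gF = NULL) {
  params <- model$params
  d <- caches$dims
  nvox <- prod(d)
  Mf <- caches$Mf
  gl <- matrix(g_logits, nvox, 1)
  gMf <- gl %*% t(params$center_w)
  gr <- list()
  gr$center_w <- t(Mf) %*% gl
  gr$center_b <- sum(gl)
  if (!is.null(gF)) {
    gFf <- matrix(gF, nvox, model$cfg$contrast_channels)
    gMf <- gMf + gFf %*% t(params$feat_w)
    gr$feat_w <- t(Mf) %*% gFf
    gr$feat_b <- colSums(gFf)
  } else {
    gr$feat_w <- array(0, dim = dim(params$feat_w))
    gr$feat_b <- numeric(length(params$feat_b))
  }
  gM <- array(gMf, dim = c(d, model$cfg$fusion_channels)) * caches$rmask
  bw3 <- cpp_conv3d_bw(caches$U, params$fusion$w, gM)
  gr$fusion <- list(w = bw3$gw, b = bw3$gb)
  gU <- bw3$gx
  genc <- NULL
  for (z in seq_len(d[3])) {
    gslice <- array(gU[, , z, ], dim = c(d[1], d[2], model$cfg$unet_channels))
    g1 <- unet2d_bw(params, caches$slices[[z]], gslice)
    genc <- if (is.null(genc)) g1 else tree_add(genc, g1)
  }
  gr$enc <- genc$enc
  gr$bott <- genc$bott
  gr$dec <- genc$dec
  gr[names(params)]
}

# dihedral (flip/rot90) transforms of a 3D array, applied in the xy plane;
# these have exact inverses, so augmented heat maps can be re-aligned voxelwise
d4_apply <- function(arr, k, flip) {
  d <- dim(arr)
  if (flip) arr <- arr[rev(seq_len(d[1])), , , drop = FALSE]
  k <- k %% 4
  if (k > 0) {
    out <- array(0, dim = d)   # square xy assumed for k odd
    for (z in seq_len(d[3])) out[, , z] <- rot90_mat(arr[, , z], k)
    arr <- out
  }
  arr
}

d4_invert <- function(arr, k, flip) {
  d <- dim(arr)
  k <- k %% 4
  if (k > 0) {
    out <- array(0, dim = d)
    for (z in seq_len(d[3])) out[, , z] <- rot90_mat(arr[, , z], 4 - k)
    arr <- out
  }
  if (flip) arr <- arr[rev(seq_len(d[1])), , , drop = FALSE]
  arr
}

d4_apply4 <- function(arr4, k, flip) {
  for (c in seq_len(dim(arr4)[4]))
    arr4[, , , c] <- d4_apply(arr4[, , , c, drop = FALSE][, , , 1], k, flip)
  arr4
}

d4_invert4 <- function(arr4, k, flip) {
  for (c in seq_len(dim(arr4)[4]))
    arr4[, , , c] <- d4_invert(arr4[, , , c, drop = FALSE][, , , 1], k, flip)
  arr4
}

# Detector-side preprocessing. Rescaling mode "standardize" denoises and
# z-scores the volume (sign-flipped so particles are bright); "equalize"
# applies the same denoise + histogram equalization as candidate proposal.
# Standardization is the default: under near-Gaussian noise, rank
# equalization compresses the informative dark intensity tail into a
# negligible value range and measurably degrades detection, while real
# tomograms with heavy-tailed intensity artifacts may still prefer
# equalization.
detector_preprocess <- function(model, vol) {
  pp <- model$preprocess
  if (is.null(pp$rescale)) pp$rescale <- "standardize"
  v <- as_volume_array(vol)
  # project onto the measurable Fourier subspace: the wedge left unsampled
  # by the tilt range carries noise only, so zeroing it denoises without
  # touching the signal (the tilt range is acquisition metadata)
  if (!is.null(pp$wedge_filter) && is.finite(pp$wedge_filter) &&
      pp$wedge_filter < 90)
    v <- apply_missing_wedge(v, pp$wedge_filter)
  if (identical(pp$rescale, "equalize")) {
    v <- preprocess_volume(v, pp$denoise_sigma, pp$bins)
    if (pp$invert) v <- 1 - v
    return(v)
  }
  if (pp$denoise_sigma > 0) v <- cpp_gauss_smooth3d(v, pp$denoise_sigma)
  s <- sd(v)
  v <- if (s > 0) (v - mean(v)) / s else v - mean(v)
  if (pp$invert) v <- -v
  v
}

#' Predict the particle-probability heat map for a whole tomogram
#'
#' Applies the model's preprocessing (denoise + equalization + contrast
#' convention) and runs the detector over the full volume; output values are
#' sigmoid probabilities in \[0, 1\] at stride 1.
#'
#' @param model a trained `detector_model`.
#' @param vol a [tomogram_volume()] or 3D array.
#' @return 3D array, same shape as the volume.
#' @export
predict_heatmap <- function(model, vol) {
  v <- detector_preprocess(model, vol)
  detector_forward(model, v, want_caches = FALSE)$yhat
}

#' Extract particle coordinates from a predicted heat map
#'
#' A voxel is kept iff it equals the 3D max-pooled value of its cubic kernel
#' neighborhood and exceeds `prob_threshold` (ties keep the
#' lexicographically smallest coordinate). Tubular mode fixes the kernel to
#' 3 so that enough coordinates survive for polynomial fitting.
#'
#' @param heat 3D probability array.
#' @param kernel odd kernel size >= 3.
#' @param prob_threshold probability threshold in (0, 1).
#' @param mode `"globular"` or `"tubular"`.
#' @param tomo_id id for the output table.
#' @return a [coord_table()] sorted by decreasing score.
#' @export
extract_particles <- function(heat, kernel = 9L, prob_threshold = 0.5,
                              mode = c("globular", "tubular"),
                              tomo_id = "tomo") {
  mode <- match.arg(mode)
  if (mode == "tubular") kernel <- 3L
  if (kernel %% 2 != 1 || kernel < 3) stop("kernel must be odd and >= 3")
  stopifnot(prob_threshold > 0, prob_threshold < 1)
  m <- cpp_local_max3d(heat, as.integer(kernel), prob_threshold)
  if (nrow(m) == 0) return(coord_table())
  ord <- order(m[, 4], decreasing = TRUE)
  coord_table(tomo_id, m[ord, 1], m[ord, 2], m[ord, 3], score = m[ord, 4])
}
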