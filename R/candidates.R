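#' Gaussian denoising plus histogram equalization
#'
#' Smooths the volume with an isotropic Gaussian (reflect-padded, separable)
#' and then applies histogram equalization over `bins` intensity bins,
#' mapping smoothed intensities through their empirical CDF onto \[0, 1\].
#' The mapping is monotone and rank-preserving. A constant volume (zero
#' intensity spread) maps to the documented degenerate value 0.5.
#'
#' @param vol a [tomogram_volume()] or 3D array.
#' @param denoise_sigma Gaussian sigma in voxels, >= 0 (0 skips smoothing).
#' @param bins number of histogram bins.
#' @return same type as input, values in \[0, 1\].
#' @export
preprocess_volume <- function(vol, denoise_sigma = 2, bins = 256L) {
  stopifnot(denoise_sigma >= 0)
  v <- as_volume_array(vol)
  sm <- if (denoise_sigma > 0) cpp_gauss_smooth3d(v, denoise_sigma) else v
  rng <- range(sm)
  if (diff(rng) == 0) {
    out <- array(0.5, dim = dim(v))
  } else {
    br <- seq(rng[1], rng[2], length.out = bins + 1L)
    idx <- findInterval(sm, br, rightmost.closed = TRUE, all.inside = TRUE)
    cdf <- cumsum(tabulate(idx, nbins = bins)) / length(sm)
    out <- array(cdf[idx], dim = dim(v))
  }
  if (inherits(vol, "tomogram_volume")) tomogram_volume(out, vol$voxel_size)
  else out
}

#' Difference-of-Gaussians pyramid response
#'
#' Smooths the volume at each sigma of a strictly increasing ladder, takes
#' successive differences DoG_i = G_i * vol - G_{i+1} * vol, and returns the
#' voxelwise maximum across pyramid levels.
#'
#' @param vol a [tomogram_volume()] or 3D array (bright-blob convention: the
#'   structures to detect must be brighter than background; invert first for
#'   dark particles).
#' @param sigmas strictly increasing vector of at least two sigmas in voxels.
#' @return a list of class `dog_response` with elements `response` (array of
#'   the source shape) and `sigmas`.
#' @export
dog_response <- function(vol, sigmas) {
  if (length(sigmas) < 2L)
    stop("need at least 2 sigmas for a DoG pyramid")
  if (any(diff(sigmas) <= 0))
    stop("sigmas must be strictly increasing")
  v <- as_volume_array(vol)
  smoothed <- lapply(sigmas, function(s) cpp_gauss_smooth3d(v, s))
  resp <- NULL
  for (i in seq_len(length(sigmas) - 1L)) {
    dg <- smoothed[[i]] - smoothed[[i + 1L]]
    resp <- if (is.null(resp)) dg else pmax(resp, dg)
  }
  resp <- array(resp, dim = dim(v))
  structure(list(response = resp, sigmas = sigmas), class = "dog_response")
}

#' Geometric sigma ladder for the DoG pyramid
#'
#' Starts at `expected_radius / sqrt(2)` and multiplies by `ratio` for
#' `levels + 1` smoothing scales (giving `levels` DoG differences).
#'
#' @param expected_radius expected particle radius in voxels.
#' @param levels number of DoG levels.
#' @param ratio geometric ratio between consecutive sigmas.
#' @export
dog_sigma_ladder <- function(expected_radius, levels = 3L, ratio = 1.6) {
  (expected_radius / sqrt(2)) * ratio^(0:levels)
}

#' Automatic response threshold
#'
#' Mean response plus 0.5 population standard deviations.
#'
#' @param resp a `dog_response` or numeric array.
#' @return scalar threshold.
#' @export
auto_threshold <- function(resp) {
  r <- if (inherits(resp, "dog_response")) resp$response else resp
  mu <- mean(r)
  mu + 0.5 * sqrt(mean((r - mu)^2))
}

#' Greedy 3D non-maximum suppression
#'
#' Visits voxels with response above `threshold` in order of decreasing
#' response (ties resolved toward the lexicographically smallest (x, y, z))
#' and keeps a voxel iff its Euclidean distance to every previously kept
#' voxel exceeds `radius`, stopping at `max_candidates`.
#'
#' @param resp a `dog_response` or numeric array.
#' @param radius exclusion radius in voxels, >= 1.
#' @param threshold response threshold (see [auto_threshold()]).
#' @param max_candidates cap on the number of returned coordinates.
#' @param tomo_id id recorded in the output table.
#' @return a [coord_table()] ordered by decreasing response, with the raw
#'   response min-max normalized to \[0, 1\] as `score`.
#' @export
nms_3d <- function(resp, radius, threshold = NULL, max_candidates = 2000L,
                   tomo_id = "tomo") {
  stopifnot(radius >= 1)
  r <- if (inherits(resp, "dog_response")) resp$response else resp
  if (is.null(threshold)) threshold <- auto_threshold(r)
  m <- cpp_nms3d(r, radius, threshold, as.integer(max_candidates))
  if (nrow(m) == 0) return(coord_table())
  rng <- range(r)
  sc <- if (diff(rng) > 0) (m[, 4] - rng[1]) / diff(rng) else rep(1, nrow(m))
  coord_table(tomo_id, m[, 1], m[, 2], m[, 3], score = sc)
}

#' Project a 3D coordinate into a tilted image
#'
#' For tilt angle theta (tilt axis y), the projected abscissa is
#' x_theta = (x - floor(W/2)) cos(theta) + (z - floor(D/2)) sin(theta) +
#' floor(W/2) and the ordinate is unchanged (y_theta = y).
#'
#' @param coord numeric (x, y, z), 0-based voxels.
#' @param theta tilt angle in degrees.
#' @param dims integer (W, D) of the volume (the tilt image is W wide).
#' @return numeric (x_theta, y_theta) with attribute `inside` indicating
#'   whether the projected point falls inside the image width.
#' @export
project_coordinate <- function(coord, theta, dims) {
  th <- theta * pi / 180
  cx <- floor(dims[1] / 2)
  cz <- floor(dims[2] / 2)
  xt <- (coord[1] - cx) * cos(th) + (coord[3] - cz) * sin(th) + cx
  out <- c(x_theta = unname(xt), y_theta = unname(coord[2]))
  attr(out, "inside") <- xt >= 0 && xt <= dims[1] - 1
  out
}

reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  j <- ((i - 1L) %% p + p) %% p
  ifelse(j >= n, p - j, j) + 1L
}

# bilinear sampling of a matrix at (possibly fractional) 0-based coordinates,
# reflect-padded outside the image
bilinear_sample <- function(img, xs, ys) {
  n <- dim(img)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  g <- function(ix, iy) {
    img[cbind(reflect_index(as.integer(ix) + 1L, n[1]),
              reflect_index(as.integer(iy) + 1L, n[2]))]
  }
  xi <- rep(x0, times = length(ys)); yi <- rep(y0, each = length(xs))
  fxi <- rep(fx, times = length(ys)); fyi <- rep(fy, each = length(xs))
  v <- (1 - fxi) * (1 - fyi) * g(xi, yi) +
       fxi * (1 - fyi) * g(xi + 1, yi) +
       (1 - fxi) * fyi * g(xi, yi + 1) +
       fxi * fyi * g(xi + 1, yi + 1)
  matrix(v, length(xs), length(ys))
}

#' Extract the (P_t, P_s) patch pair for one candidate
#'
#' P_s is a square patch from the central tomographic slice at the
#' candidate's z. P_t is the mean of patches sampled (bilinearly) from every
#' tilt image whose angle magnitude is within `angle_window`, each centered
#' at the Eq-style projected coordinate. Patches crossing the image border
#' are reflect-padded and flagged. With no tilt series (or an empty angular
#' window, with a warning) P_t falls back to P_s.
#'
#' @param vol a [tomogram_volume()] or 3D array.
#' @param tilts a [tilt_series()] or `NULL` for P_s-only mode.
#' @param coord numeric (x, y, z) in 0-based voxels.
#' @param patch_side patch side length in voxels.
#' @param angle_window half-width of the tilt window in degrees.
#' @return a list of class `patch_pair` with `P_t`, `P_s` (side x side
#'   matrices), `coord`, `side` and `border_flagged`.
#' @export
extract_pair <- function(vol, tilts, coord, patch_side = 32L,
                         angle_window = 15) {
  v <- as_volume_array(vol)
  d <- dim(v)
  s <- as.integer(patch_side)
  offs <- seq_len(s) - (s + 1) / 2
  flagged <- FALSE
  samp <- function(img, cx, cy) {
    xs <- cx + offs; ys <- cy + offs
    if (min(xs) < 0 || min(ys) < 0 ||
        max(xs) > dim(img)[1] - 1 || max(ys) > dim(img)[2] - 1)
      flagged <<- TRUE
    bilinear_sample(img, xs, ys)
  }
  zi <- min(max(round(coord[3]), 0), d[3] - 1)
  P_s <- samp(v[, , zi + 1], coord[1], coord[2])
  if (is.null(tilts)) {
    P_t <- P_s
  } else {
    sel <- which(abs(tilts$angles) <= angle_window)
    used <- 0L
    acc <- matrix(0, s, s)
    for (i in sel) {
      pj <- project_coordinate(coord, tilts$angles[i],
                               c(d[1], d[3]))
      if (!attr(pj, "inside")) next   # flagged: skip this tilt
      acc <- acc + samp(tilts$images[[i]], pj[1], pj[2])
      used <- used + 1L
    }
    if (used == 0L) {
      warning("no usable tilts within the angular window; ",
              "falling back to P_s-only mode")
      P_t <- P_s
    } else P_t <- acc / used
  }
  structure(list(P_t = P_t, P_s = P_s, coord = as.numeric(coord[1:3]),
                 side = s, border_flagged = flagged),
            class = "patch_pair")
}

#' Propose candidate coordinates from a tomogram
#'
#' Convenience wrapper: preprocess (denoise + equalize), optionally invert
#' (dark-particle convention), DoG pyramid at a geometric sigma ladder,
#' automatic thresholding and greedy 3D NMS.
#'
#' @param vol a [tomogram_volume()] or 3D array.
#' @param cfg a [default_config()]-style configuration.
#' @param threshold response threshold; `NULL` uses [auto_threshold()].
#' @return list with `coords` (a [coord_table()]), `response` and
#'   `threshold`.
#' @export
propose_candidates <- function(vol, cfg = default_config(), threshold = NULL) {
  pre <- preprocess_volume(vol, cfg$denoise_sigma, cfg$hist_bins)
  p <- as_volume_array(pre)
  if (cfg$invert_contrast) p <- 1 - p
  resp <- dog_response(p, dog_sigma_ladder(cfg$expected_radius,
                                           cfg$dog_levels,
                                           cfg$dog_sigma_ratio))
  if (is.null(threshold)) threshold <- auto_threshold(resp)
  coords <- nms_3d(resp, cfg$nms_radius, threshold, cfg$max_candidates)
  list(coords = coords, response = resp$response, threshold = threshold)
}
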