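#' Synthetic scene specification
#'
#' Describes a ground-truthed synthetic tomogram: cosine-tapered dark spheres
#' (globular particles), curved tubes whose centerlines follow
#' x = a0 + b0*y + c0*y^2, z = a1 + b1*y + c1*y^2, an optional membrane-like
#' sheet, point-like fiducials, a Fourier-domain missing wedge and additive
#' Gaussian noise. Defaults generate the scaled study scene used throughout
#' the package tests: a 64 x 64 x 32 volume holding 30 spheres of radius 4
#' with a 60-degree wedge and noise at 0.7 of the signal peak-to-peak.
#'
#' @param shape integer (W, H, D).
#' @param n_spheres number of globular particles.
#' @param sphere_radius radius range (min, max) in voxels.
#' @param n_tubes number of tubular particles.
#' @param tube_radius tube cross-section radius in voxels.
#' @param tube_curve_max magnitude bound on the quadratic path coefficients.
#' @param include_membrane add a curved membrane-like sheet.
#' @param n_fiducials number of small high-density dots.
#' @param wedge_half_angle missing-wedge half angle in degrees (90 = none).
#' @param noise_sigma Gaussian noise s.d. as a fraction of the signal
#'   peak-to-peak amplitude.
#' @param amplitude particle contrast amplitude.
#' @param dark_particles if `TRUE` (cryo-ET convention) particles are darker
#'   than the background.
#' @param seed RNG seed; rendering is deterministic given the seed.
#' @return a list of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(64L, 64L, 32L), n_spheres = 30L,
                       sphere_radius = c(4, 4), n_tubes = 0L,
                       tube_radius = 2, tube_curve_max = 0.015,
                       include_membrane = FALSE, n_fiducials = 0L,
                       wedge_half_angle = 60, noise_sigma = 0.7,
                       amplitude = 1, dark_particles = TRUE, seed = 0L) {
  if (length(sphere_radius) == 1L) sphere_radius <- rep(sphere_radius, 2)
  stopifnot(n_spheres >= 0, n_tubes >= 0, n_fiducials >= 0,
            wedge_half_angle > 0, wedge_half_angle <= 90,
            all(sphere_radius >= 1), tube_radius >= 1, noise_sigma >= 0)
  structure(as.list(environment()), class = "scene_spec")
}

splat_ball <- function(vox, center, radius, amp) {
  d <- dim(vox)
  lo <- pmax(floor(center - radius), 0)
  hi <- pmin(ceiling(center + radius), d - 1)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx2 <- (xs - center[1])^2
  dy2 <- (ys - center[2])^2
  dz2 <- (zs - center[3])^2
  dd <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
  prof <- ifelse(dd <= radius, 0.5 * (1 + cos(pi * dd / radius)), 0)
  block <- vox[xs + 1, ys + 1, zs + 1, drop = FALSE]
  vox[xs + 1, ys + 1, zs + 1] <- block - amp * array(prof, dim(block))
  vox
}

place_centers <- function(n, dims, radius, min_sep, existing, max_tries = 400) {
  if (n > 0 && any(dims - radius - 2 < radius + 1))
    stop("placement error: volume too small for the requested particles")
  centers <- existing
  out <- matrix(0, 0, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      c0 <- c(runif(1, radius + 1, dims[1] - radius - 2),
              runif(1, radius + 1, dims[2] - radius - 2),
              runif(1, radius + 1, dims[3] - radius - 2))
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums((centers - matrix(c0, nrow(centers), 3,
                                             byrow = TRUE))^2))) >= min_sep) {
        centers <- rbind(centers, c0)
        out <- rbind(out, c0)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("placement error: volume too small for the requested particles")
  }
  list(new = out, all = centers)
}

#' Render a synthetic tomogram with known ground truth
#'
#' Deterministic given `spec$seed`. Particle centers are separated by at
#' least 1.5x the maximum particle radius. Returns both the degraded volume
#' (wedge + noise) and the clean render, plus per-class ground truth; tube
#' ground truth carries the generating polynomial coefficients and dense
#' centerline samples.
#'
#' @param spec a [scene_spec()].
#' @return list with elements `volume` (a [tomogram_volume()]), `clean`
#'   (noise-free, wedge-free [tomogram_volume()]) and `ground_truth` (list
#'   with `spheres`, `fiducials` [coord_table()]s and `tubes`).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  d <- as.integer(spec$shape)
  vox <- array(1, dim = d)
  centers <- matrix(0, 0, 3)
  min_sep <- 1.5 * max(spec$sphere_radius)

  # tubes are placed first (their centerlines are extended obstacles and are
  # much harder to fit once spheres occupy the volume)
  tubes <- list()
  for (ti in seq_len(spec$n_tubes)) {
    for (try in seq_len(200)) {
      y0 <- 2; y1 <- d[2] - 3
      ym <- (y0 + y1) / 2
      b0 <- runif(1, -0.4, 0.4); c0 <- runif(1, -1, 1) * spec$tube_curve_max
      b1 <- runif(1, -0.15, 0.15); c1 <- runif(1, -1, 1) * spec$tube_curve_max / 2
      a0 <- runif(1, d[1] * 0.2, d[1] * 0.8) - b0 * ym - c0 * ym^2
      a1 <- runif(1, d[3] * 0.3, d[3] * 0.7) - b1 * ym - c1 * ym^2
      ys <- seq(y0, y1, by = 0.5)
      xs <- a0 + b0 * ys + c0 * ys^2
      zs <- a1 + b1 * ys + c1 * ys^2
      m <- spec$tube_radius + 1
      if (all(xs > m & xs < d[1] - 1 - m & zs > m & zs < d[3] - 1 - m)) {
        ok_sep <- TRUE
        if (nrow(centers) > 0) {
          for (k in seq_along(ys)) {
            dd <- sqrt(rowSums((centers - matrix(c(xs[k], ys[k], zs[k]),
                                                 nrow(centers), 3,
                                                 byrow = TRUE))^2))
            if (min(dd) < min_sep) { ok_sep <- FALSE; break }
          }
        }
        if (!ok_sep) next
        for (k in seq_along(ys))
          vox <- splat_ball(vox, c(xs[k], ys[k], zs[k]), spec$tube_radius,
                            spec$amplitude * 0.35)
        cl <- cbind(x = xs, y = ys, z = zs)
        tubes[[length(tubes) + 1]] <-
          list(coefficients = c(a0 = a0, b0 = b0, c0 = c0,
                                a1 = a1, b1 = b1, c1 = c1),
               y_range = c(y0, y1), centerline = cl)
        centers <- rbind(centers, cl[seq(1, nrow(cl), by = 4), ])
        break
      }
      if (try == 200)
        stop("placement error: could not fit the requested tubes")
    }
  }

  radii <- if (spec$n_spheres > 0)
    runif(spec$n_spheres, spec$sphere_radius[1], spec$sphere_radius[2]) else numeric()
  sph <- place_centers(spec$n_spheres, d, max(spec$sphere_radius), min_sep,
                       centers)
  centers <- sph$all
  for (i in seq_len(spec$n_spheres))
    vox <- splat_ball(vox, sph$new[i, ], radii[i], spec$amplitude)

  if (spec$include_membrane) {
    z0 <- d[3] * 0.75
    for (x in 0:(d[1] - 1)) {
      zc <- z0 + 2 * sin(2 * pi * x / (2 * d[1]))
      zs <- 0:(d[3] - 1)
      prof <- ifelse(abs(zs - zc) <= 1.5,
                     0.5 * (1 + cos(pi * abs(zs - zc) / 1.5)), 0)
      vox[x + 1, , ] <- vox[x + 1, , ] -
        spec$amplitude * 0.6 * matrix(prof, d[2], d[3], byrow = TRUE)
    }
  }

  fid <- place_centers(spec$n_fiducials, d, 2, min_sep, centers)
  for (i in seq_len(spec$n_fiducials))
    vox <- splat_ball(vox, fid$new[i, ], 1.5, spec$amplitude * 3)

  if (!spec$dark_particles) vox <- 2 - vox   # invert contrast about background

  clean <- vox
  if (spec$wedge_half_angle < 90)
    vox <- apply_missing_wedge(vox, spec$wedge_half_angle)
  if (spec$noise_sigma > 0)
    vox <- add_noise_array(vox, spec$noise_sigma, seed = spec$seed + 1L)

  gt <- list(
    spheres = coord_table("synthetic", sph$new[, 1], sph$new[, 2],
                          sph$new[, 3],
                          label = rep(1L, spec$n_spheres)),
    fiducials = coord_table("synthetic", fid$new[, 1], fid$new[, 2],
                            fid$new[, 3],
                            label = rep(3L, spec$n_fiducials)),
    tubes = tubes)
  list(volume = tomogram_volume(vox), clean = tomogram_volume(clean),
       ground_truth = gt)
}

#' Parallel-beam tilt projection of a volume
#'
#' Each image is the line integral of the volume along the beam direction
#' after rotating the (x, z) plane by theta about the y (tilt) axis; a voxel
#' at (x, y, z) contributes at abscissa
#' x_theta = (x - floor(W/2)) cos(theta) + (z - floor(D/2)) sin(theta) +
#' floor(W/2), split between the two nearest pixels by linear weights.
#'
#' @param vol a [tomogram_volume()] or 3D array.
#' @param angles tilt angles in degrees, strictly increasing, |theta| < 90.
#' @return a [tilt_series()] of (W, H) images.
#' @export
simulate_tilt_series <- function(vol, angles) {
  v <- as_volume_array(vol)
  d <- dim(v)
  W <- d[1]; H <- d[2]; D <- d[3]
  if (any(abs(angles) >= 90)) stop("tilt angles must satisfy |theta| < 90")
  cx <- floor(W / 2); cz <- floor(D / 2)
  # (x,z) plane flattened against y: rows index (x,z), cols index y
  flat <- matrix(aperm(v, c(1, 3, 2)), nrow = W * D, ncol = H)
  xs <- rep(0:(W - 1), times = D)
  zs <- rep(0:(D - 1), each = W)
  images <- lapply(angles, function(theta) {
    th <- theta * pi / 180
    xt <- (xs - cx) * cos(th) + (zs - cz) * sin(th) + cx
    i0 <- floor(xt)
    w1 <- xt - i0
    rows <- c(i0, i0 + 1)
    wts <- c(1 - w1, w1)
    src <- c(seq_len(W * D), seq_len(W * D))
    keep <- rows >= 0 & rows <= W - 1 & wts > 0
    S <- Matrix::sparseMatrix(i = rows[keep] + 1, j = src[keep],
                              x = wts[keep], dims = c(W, W * D))
    as.matrix(S %*% flat)
  })
  tilt_series(images, angles)
}

#' Zero the missing-wedge region of a volume's Fourier transform
#'
#' Coefficients whose (k_x, k_z) direction lies more than `half_angle`
#' degrees away from the k_z = 0 plane are set to zero (the unsampled wedge
#' around the beam axis left by a limited tilt range); the operator is
#' idempotent and returns a real volume.
#'
#' @param vol a [tomogram_volume()] or 3D array.
#' @param half_angle wedge half-angle in degrees, in (0, 90].
#' @return same type as the input.
#' @export
apply_missing_wedge <- function(vol, half_angle) {
  stopifnot(half_angle > 0, half_angle <= 90)
  v <- as_volume_array(vol)
  d <- dim(v)
  freq <- function(n) { f <- 0:(n - 1); f[f > n / 2] <- f[f > n / 2] - n; f / n }
  fx <- freq(d[1]); fz <- freq(d[3])
  ang <- atan2(abs(rep(fz, each = d[1])), abs(rep(fx, times = d[3])))
  keep <- ang <= half_angle * pi / 180 + 1e-12
  mask_xz <- matrix(keep, d[1], d[3])
  F <- fft(v)
  mask <- aperm(array(mask_xz, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  F[!mask] <- 0
  out <- Re(fft(F, inverse = TRUE)) / length(F)
  if (inherits(vol, "tomogram_volume")) tomogram_volume(out, vol$voxel_size)
  else out
}

add_noise_array <- function(v, sigma, seed) {
  set.seed(seed)
  p2p <- diff(range(v))
  if (p2p == 0) p2p <- 1   # degenerate constant volume: unit signal scale
  v + array(rnorm(length(v), sd = sigma * p2p), dim = dim(v))
}

#' Add i.i.d. Gaussian noise scaled by the signal peak-to-peak amplitude
#'
#' The noise standard deviation is `sigma` times the volume's peak-to-peak
#' range (a constant volume falls back to a unit signal scale). Deterministic
#' given `seed`.
#'
#' @param vol a [tomogram_volume()] or 3D array.
#' @param sigma noise level as a fraction of the signal amplitude, >= 0.
#' @param seed RNG seed.
#' @return same type as the input.
#' @export
add_noise <- function(vol, sigma, seed = 0L) {
  stopifnot(sigma >= 0)
  v <- as_volume_array(vol)
  out <- if (sigma == 0) v else add_noise_array(v, sigma, seed)
  if (inherits(vol, "tomogram_volume")) tomogram_volume(out, vol$voxel_size)
  else out
}
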