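#' Build the voxel-level target heat map from sparse annotations
#'
#' Globular mode splats a Gaussian kernel exp(-||v - p||^2 / (2 sigma_k^2))
#' at each annotated center (value exactly 1 at the center voxel), taking
#' the elementwise maximum where annotations overlap; the Gaussian support
#' is truncated at 3 sigma_k. Tubular mode sets all voxels within a
#' Euclidean radius (default 3) of each annotation to 1. Every voxel not
#' covered by any annotation support is unlabeled and carries the value -1.
#'
#' @param coords a [coord_table()] of annotated centers (0-based voxels).
#' @param shape integer (W, H, D) of the target.
#' @param mode `"globular"` or `"tubular"`.
#' @param sigma_k Gaussian kernel sigma (globular), set by the particle size.
#' @param radius ball radius for tubular targets.
#' @return a list of class `target_heatmap` with `Y` (array in \[-1, 1\]),
#'   `mode` and the kernel parameter.
#' @export
make_target_heatmap <- function(coords, shape, mode = c("globular", "tubular"),
                                sigma_k = 2, radius = 3) {
  mode <- match.arg(mode)
  validate_coords(coords, shape)
  Y <- array(-1, dim = shape)
  supp <- if (mode == "globular") 3 * sigma_k else radius
  for (i in seq_len(nrow(coords))) {
    p <- floor(c(coords$x[i], coords$y[i], coords$z[i]))
    lo <- pmax(floor(p - supp), 0)
    hi <- pmin(ceiling(p + supp), shape - 1)
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    d2 <- outer(outer((xs - p[1])^2, (ys - p[2])^2, "+"), (zs - p[3])^2, "+")
    if (mode == "globular") {
      val <- exp(-d2 / (2 * sigma_k^2))
      val[sqrt(d2) > supp] <- -1
    } else {
      val <- ifelse(sqrt(d2) <= radius, 1, -1)
    }
    blk <- Y[xs + 1, ys + 1, zs + 1, drop = FALSE]
    Y[xs + 1, ys + 1, zs + 1] <- pmax(blk, array(val, dim(blk)))
  }
  if (nrow(coords) > 0 && !any(Y == 1))
    stop("internal error: no target voxel reached 1")  # nocov
  structure(list(Y = Y, mode = mode,
                 sigma_k = if (mode == "globular") sigma_k else NA_real_,
                 radius = if (mode == "tubular") radius else NA_real_),
            class = "target_heatmap")
}
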