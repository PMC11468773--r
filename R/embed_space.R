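#' Reduce embeddings to a normalized 2D layout
#'
#' Nonlinear neighbor-graph embedding: a symmetrized k-nearest-neighbor
#' graph (default `n_neighbors = 40`) is built on the 128-d embeddings,
#' geodesic (shortest-path) distances are computed per connected component
#' and embedded by classical MDS; components are laid out side by side with
#' a gap controlled by `min_dist`, and the result is min-max normalized to
#' the unit square. Deterministic given `seed` (randomness only breaks
#' exact ties in degenerate zero-spread components).
#'
#' @param embeddings numeric matrix (n x d), one row per candidate.
#' @param n_neighbors neighborhood size of the kNN graph.
#' @param min_dist relative gap between disconnected components.
#' @param seed RNG seed.
#' @return a list of class `planar_embedding` with `coords` (n x 2 in
#'   \[0,1\]^2) and `colors` (n x 3 in \[0,1\], the (u, v, 1-(u+v)/2) map).
#' @export
reduce_to_2d <- function(embeddings, n_neighbors = 40L, min_dist = 0.1,
                         seed = 0L) {
  n <- nrow(embeddings)
  if (n < n_neighbors + 1)
    stop("too few points (", n, ") for n_neighbors = ", n_neighbors,
         "; reduce n_neighbors")
  set.seed(seed)
  dm <- as.matrix(dist(embeddings))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(dm[i, ])[2:(n_neighbors + 1)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj * dm, mode = "undirected",
                                           weighted = TRUE)
  comp <- igraph::components(g)
  coords <- matrix(0, n, 2)
  offset_x <- 0
  for (ci in seq_len(comp$no)) {
    idx <- which(comp$membership == ci)
    if (length(idx) == 1) {
      coords[idx, ] <- c(offset_x, 0)
      offset_x <- offset_x + max(min_dist, 0.05)
      next
    }
    gd <- igraph::distances(g, v = idx, to = idx)
    spread <- max(gd)
    if (spread == 0) {
      # all-identical component: collapse to a jittered point cloud
      xy <- matrix(rnorm(2 * length(idx), sd = 1e-6), ncol = 2)
    } else {
      xy <- cmdscale(stats::as.dist(gd), k = 2)
      if (ncol(xy) < 2) xy <- cbind(xy, 0)
    }
    xy[, 1] <- xy[, 1] - min(xy[, 1])
    xy[, 2] <- xy[, 2] - mean(xy[, 2])
    coords[idx, ] <- cbind(xy[, 1] + offset_x, xy[, 2])
    width <- max(xy[, 1])
    scale_ref <- max(width, max(xy[, 2]) - min(xy[, 2]), 1e-12)
    offset_x <- offset_x + width + max(min_dist, 0.05) * max(scale_ref, 1)
  }
  rng1 <- range(coords[, 1]); rng2 <- range(coords[, 2])
  coords[, 1] <- if (diff(rng1) > 0) (coords[, 1] - rng1[1]) / diff(rng1)
                 else rep(0.5, n)
  coords[, 2] <- if (diff(rng2) > 0) (coords[, 2] - rng2[1]) / diff(rng2)
                 else rep(0.5, n)
  structure(list(coords = coords, colors = planar_colors(coords)),
            class = "planar_embedding")
}

planar_colors <- function(coords) {
  cbind(r = coords[, 1], g = coords[, 2],
        b = 1 - (coords[, 1] + coords[, 2]) / 2)
}

#' Over-cluster embeddings: k-means then spectral regrouping
#'
#' Vanilla k-means with `k` centers (k much larger than the expected class
#' count) on the 128-d embeddings, followed by spectral clustering of the k
#' centers into `h` final labels (Gaussian affinity with bandwidth equal to
#' the median inter-center distance, normalized-Laplacian embedding,
#' k-means on the leading eigenvectors). Each candidate inherits the final
#' label of its k-means center.
#'
#' @param embeddings numeric matrix (n x d).
#' @param k number of initial k-means clusters (<= n).
#' @param h number of final labels (<= k).
#' @param seed RNG seed.
#' @return a list of class `cluster_assignment` with `initial` (1..k),
#'   `final` (1..h), and `centroids` (h x d, per-final-label means).
#' @export
over_cluster <- function(embeddings, k, h, seed = 0L) {
  n <- nrow(embeddings)
  if (k > n) stop("k (", k, ") exceeds the number of points (", n, ")")
  if (h > k) stop("h must not exceed k")
  set.seed(seed)
  if (k == n) {
    km <- list(cluster = seq_len(n), centers = embeddings)
  } else {
    km <- kmeans(embeddings, centers = k, nstart = 5, iter.max = 50)
  }
  centers <- km$centers
  final_of_center <- if (h == k) seq_len(k) else
    spectral_regroup(centers, h)
  final <- final_of_center[km$cluster]
  centroids <- do.call(rbind, lapply(seq_len(h), function(l) {
    rows <- embeddings[final == l, , drop = FALSE]
    if (nrow(rows) == 0) rep(NA_real_, ncol(embeddings)) else colMeans(rows)
  }))
  structure(list(initial = km$cluster, final = final, centroids = centroids,
                 k = k, h = h),
            class = "cluster_assignment")
}

spectral_regroup <- function(centers, h) {
  k <- nrow(centers)
  dm <- as.matrix(dist(centers))
  band <- stats::median(dm[upper.tri(dm)])
  if (!is.finite(band) || band == 0) band <- 1
  A <- exp(-dm^2 / (2 * band^2))
  diag(A) <- 0
  dsqrt <- 1 / sqrt(pmax(rowSums(A), 1e-12))
  L <- diag(k) - (dsqrt * A) %*% diag(dsqrt)   # normalized Laplacian
  ev <- eigen(L, symmetric = TRUE)
  U <- ev$vectors[, k - seq_len(h) + 1, drop = FALSE]  # h smallest
  nr <- sqrt(rowSums(U^2))
  U <- U / ifelse(nr > 0, nr, 1)
  kmeans(U, centers = h, nstart = 10, iter.max = 50)$cluster
}

#' Select candidate coordinates by final cluster label
#'
#' The non-interactive stand-in for lasso selection: returns the rows of the
#' candidate table whose final label is in `labels`; this table is the
#' few-shot training input for the localization stage.
#'
#' @param assign a `cluster_assignment` from [over_cluster()].
#' @param coords the candidate [coord_table()] (same order as the
#'   embeddings).
#' @param labels set of final labels to keep.
#' @return the selected [coord_table()] with `label` filled in.
#' @export
select_coords_by_label <- function(assign, coords, labels) {
  if (!all(labels %in% assign$final))
    stop("labels not present in the assignment: ",
         paste(setdiff(labels, assign$final), collapse = ", "))
  keep <- assign$final %in% labels
  if (!any(keep)) warning("empty selection")
  out <- coords[keep, , drop = FALSE]
  out$label <- assign$final[keep]
  class(out) <- c("coord_table", "data.frame")
  out
}

#' Paint candidate positions into a colorized volume
#'
#' Produces a 3-channel volume: grayscale background (the input volume
#' min-max normalized) with a colored ball of the given radius at each
#' candidate, colored by its normalized planar coordinates via
#' RGB = (u, v, 1 - (u + v) / 2).
#'
#' @param vol a [tomogram_volume()] or 3D array.
#' @param coords a [coord_table()] of candidates.
#' @param planar a `planar_embedding` with one row per candidate.
#' @param radius ball radius in voxels.
#' @return 4D array (W, H, D, 3) with values in \[0, 1\].
#' @export
colorize_volume <- function(vol, coords, planar, radius = 3) {
  v <- as_volume_array(vol)
  d <- dim(v)
  rng <- range(v)
  gray <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else array(0.5, d)
  out <- array(rep(gray, 3), dim = c(d, 3))
  n <- nrow(coords)
  if (n > 0 && nrow(planar$coords) != n)
    stop("need one planar point per coordinate")
  for (i in seq_len(n)) {
    ctr <- c(coords$x[i], coords$y[i], coords$z[i])
    col <- planar$colors[i, ]
    lo <- pmax(floor(ctr - radius), 0)
    hi <- pmin(ceiling(ctr + radius), d - 1)
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    dd <- sqrt(outer(outer((xs - ctr[1])^2, (ys - ctr[2])^2, "+"),
                     (zs - ctr[3])^2, "+"))
    inside <- dd <= radius
    for (c3 in 1:3) {
      blk <- out[xs + 1, ys + 1, zs + 1, c3]
      blk[inside] <- col[c3]
      out[xs + 1, ys + 1, zs + 1, c3] <- blk
    }
  }
  out
}
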