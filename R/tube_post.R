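#' Group coordinates into connected components by distance
#'
#' Builds the undirected graph with an edge between every pair of points at
#' Euclidean distance <= `cutoff` and returns its connected components,
#' ordered by their smallest member row index (members in row order).
#'
#' @param coords a [coord_table()].
#' @param cutoff edge distance cutoff in voxels, > 0.
#' @return list of integer vectors of row indices into `coords`.
#' @export
group_by_distance <- function(coords, cutoff) {
  stopifnot(cutoff > 0)
  n <- nrow(coords)
  if (n == 0) return(list())
  dm <- as.matrix(dist(cbind(coords$x, coords$y, coords$z)))
  adj <- dm <= cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- unname(split(seq_len(n), comp))
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, min, integer(1)))]
}

#' Fit a second-order polynomial tube model to a coordinate group
#'
#' Least-squares quadratics x = a0 + b0*y + c0*y^2 and z = a1 + b1*y +
#' c1*y^2 fitted separately, parameterized by y. The residual is the RMS of
#' the combined x and z fit residuals. Groups with fewer than 6 points are
#' rejected (`too short`); groups with no y spread are rejected
#' (`not y-parameterizable`).
#'
#' @param coords a [coord_table()] (or data.frame with x, y, z) holding the
#'   group members.
#' @return a list of class `tube_model` (fields `coefficients`, `residual`,
#'   `max_curvature`, `y_range`, `members`), or a `tube_rejection` object
#'   whose `reason` field says why the group was dropped.
#' @export
fit_tube <- function(coords) {
  n <- nrow(coords)
  reject <- function(reason)
    structure(list(reason = reason), class = "tube_rejection")
  if (n < 6) return(reject("too short"))
  if (diff(range(coords$y)) < 1e-9) return(reject("not y-parameterizable"))
  y <- coords$y
  fx <- lm(x ~ y + I(y^2), data = data.frame(x = coords$x, y = y))
  fz <- lm(x ~ y + I(y^2), data = data.frame(x = coords$z, y = y))
  cf <- c(a0 = unname(coef(fx)[1]), b0 = unname(coef(fx)[2]),
          c0 = unname(coef(fx)[3]),
          a1 = unname(coef(fz)[1]), b1 = unname(coef(fz)[2]),
          c1 = unname(coef(fz)[3]))
  resid2 <- c(stats::residuals(fx)^2, stats::residuals(fz)^2)
  model <- structure(
    list(coefficients = cf,
         residual = sqrt(mean(resid2)),
         y_range = range(y),
         members = as.data.frame(coords)[, c("x", "y", "z")]),
    class = "tube_model")
  model$max_curvature <- tube_max_curvature(model)
  model
}

#' Maximum curvature of a fitted tube
#'
#' Evaluates the plane-curve curvature kappa(y) = |2c| / (1 + (b + 2cy)^2)^(3/2)
#' of each quadratic (x-on-y and z-on-y) on a dense y grid over the fit range
#' and returns the largest value.
#'
#' @param model a `tube_model` from [fit_tube()].
#' @param y_range range of y over which to evaluate; defaults to the fit's.
#' @param step y grid step.
#' @return scalar maximum curvature, >= 0.
#' @export
tube_max_curvature <- function(model, y_range = model$y_range, step = 0.1) {
  ys <- seq(y_range[1], y_range[2], by = step)
  if (length(ys) == 0 || ys[length(ys)] < y_range[2])
    ys <- c(ys, y_range[2])
  cf <- model$coefficients
  kap <- function(b, c) abs(2 * c) / (1 + (b + 2 * c * ys)^2)^(3 / 2)
  max(kap(cf["b0"], cf["c0"]), kap(cf["b1"], cf["c1"]))
}

#' Resample a fitted tube at uniform y steps
#'
#' Walks y from ymin upward in steps of `step` (inclusive start; the last
#' grid point is the largest not exceeding ymax) and evaluates the fitted
#' quadratics for x and z. Points outside `dims` (when given) are dropped.
#'
#' @param model a `tube_model`.
#' @param step y step size (the tubular pipeline default is 2).
#' @param dims optional (W, H, D) bounds for dropping out-of-volume points.
#' @param tomo_id id for the output table.
#' @return a [coord_table()] of resampled centerline points.
#' @export
resample_tube <- function(model, step = 2, dims = NULL, tomo_id = "tomo") {
  yr <- model$y_range
  if (yr[2] < yr[1]) return(coord_table())
  ys <- seq(yr[1], yr[2], by = step)
  cf <- model$coefficients
  xs <- cf["a0"] + cf["b0"] * ys + cf["c0"] * ys^2
  zs <- cf["a1"] + cf["b1"] * ys + cf["c1"] * ys^2
  keep <- rep(TRUE, length(ys))
  if (!is.null(dims))
    keep <- xs >= 0 & xs < dims[1] & ys >= 0 & ys < dims[2] &
            zs >= 0 & zs < dims[3]
  coord_table(tomo_id, xs[keep], ys[keep], zs[keep])
}

#' Filter tube models on residual and curvature cutoffs
#'
#' Keeps a model iff residual < `residual_cutoff` AND maximum curvature <
#' `curvature_cutoff` (strict inequalities).
#'
#' @param models list of `tube_model`s.
#' @param residual_cutoff,curvature_cutoff positive cutoffs.
#' @return the kept sublist.
#' @export
filter_tubes <- function(models, residual_cutoff, curvature_cutoff) {
  stopifnot(residual_cutoff > 0, curvature_cutoff > 0)
  keep <- vapply(models, function(m)
    m$residual < residual_cutoff && m$max_curvature < curvature_cutoff,
    logical(1))
  models[keep]
}

#' Trace filaments from dense tubular detections
#'
#' End-to-end tubular post-processing: distance grouping, per-group
#' quadratic fitting (short or non-parameterizable groups dropped),
#' residual/curvature filtering and uniform resampling.
#'
#' @param coords a [coord_table()] of dense tubular detections.
#' @param cutoff grouping distance cutoff in voxels.
#' @param residual_cutoff,curvature_cutoff filtering cutoffs.
#' @param step resampling step along y.
#' @param dims optional volume bounds (W, H, D).
#' @return list with `tubes` (kept `tube_model`s) and `coords` (a
#'   [coord_table()] of resampled points, labeled by tube index).
#' @export
trace_tubes <- function(coords, cutoff = 6, residual_cutoff = 1.5,
                        curvature_cutoff = 0.1, step = 2, dims = NULL) {
  groups <- group_by_distance(coords, cutoff)
  models <- list()
  for (g in groups) {
    m <- fit_tube(coords[g, ])
    if (inherits(m, "tube_model")) models[[length(models) + 1L]] <- m
  }
  kept <- filter_tubes(models, residual_cutoff, curvature_cutoff)
  out <- coord_table()
  for (i in seq_along(kept)) {
    rs <- resample_tube(kept[[i]], step, dims)
    if (nrow(rs) > 0) {
      rs$label <- i
      out <- rbind(out, rs)
    }
  }
  class(out) <- c("coord_table", "data.frame")
  list(tubes = kept, coords = out)
}
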