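#' Greedy radius-tolerant matching of predictions to ground truth
#'
#' Predictions are visited in order of decreasing score (table order is kept
#' for untied/unscored rows); each one claims the nearest still-unclaimed
#' ground-truth point within `radius` (hit, y_i = 1) or is a false positive
#' (y_i = 0). Each ground-truth point is claimed at most once.
#'
#' @param pred a [coord_table()] of predictions (scores optional).
#' @param gt a [coord_table()] of ground-truth positions.
#' @param radius match radius in voxels, > 0.
#' @return integer vector of per-prediction hit flags, in the score-sorted
#'   order, with the sort permutation as attribute `order`.
#' @export
greedy_match <- function(pred, gt, radius) {
  stopifnot(radius > 0)
  n <- nrow(pred)
  ord <- if (all(is.na(pred$score))) seq_len(n)
         else order(pred$score, decreasing = TRUE)
  flags <- integer(n)
  if (n == 0 || nrow(gt) == 0) {
    attr(flags, "order") <- ord
    return(flags)
  }
  gx <- gt$x; gy <- gt$y; gz <- gt$z
  claimed <- rep(FALSE, nrow(gt))
  r2 <- radius^2
  for (i in seq_len(n)) {
    p <- pred[ord[i], ]
    d2 <- (gx - p$x)^2 + (gy - p$y)^2 + (gz - p$z)^2
    d2[claimed] <- Inf
    j <- which.min(d2)
    if (d2[j] <= r2) {
      flags[i] <- 1L
      claimed[j] <- TRUE
    }
  }
  attr(flags, "order") <- ord
  flags
}

#' Precision, recall and F1 from greedy-match hit flags
#'
#' TP(k) is the number of hits among the top k predictions; precision is
#' TP(k)/k, recall is TP(k)/n_gt, and F1 their harmonic mean (0 when both
#' are 0). k = 0 yields precision 0 with `undefined_precision = TRUE`.
#'
#' @param flags hit flags from [greedy_match()].
#' @param n_gt number of ground-truth points.
#' @param k number of top predictions to score (default: all).
#' @return a list of class `match_report`.
#' @export
precision_recall_f1 <- function(flags, n_gt, k = length(flags)) {
  stopifnot(k <= length(flags))
  tp <- if (k > 0) sum(flags[seq_len(k)]) else 0L
  undefined <- k == 0
  pr <- if (k > 0) tp / k else 0
  re <- if (n_gt > 0) tp / n_gt else 0
  f1 <- if (pr + re > 0) 2 * pr * re / (pr + re) else 0
  structure(list(k = k, tp = tp, precision = pr, recall = re, f1 = f1,
                 n_gt = n_gt, undefined_precision = undefined),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report k=%d TP=%d Pr=%.3f Re=%.3f F1=%.3f>\n",
              x$k, x$tp, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Evaluate a prediction table against ground truth
#'
#' @param pred,gt [coord_table()]s.
#' @param radius match radius in voxels.
#' @return a `match_report` (see [precision_recall_f1()]) with the match
#'   radius attached.
#' @export
evaluate_detection <- function(pred, gt, radius) {
  flags <- greedy_match(pred, gt, radius)
  rep <- precision_recall_f1(flags, n_gt = nrow(gt))
  rep$match_radius <- radius
  rep
}
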