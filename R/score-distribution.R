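#' Exact score distribution of a weight matrix under the background
#'
#' Computes the distribution of a single window's log-odds score under
#' i.i.d. background bases, exactly, by rounding each weight to an integer
#' multiple of `granularity` and convolving the per-position score
#' distributions. Tail probabilities `P(score >= s)` give per-window
#' p-values; [threshold_for_pvalue()] inverts them into scan thresholds.
#'
#' Rounding moves any achievable score by at most `width * granularity / 2`;
#' the probability mass on the rounded lattice is exact.
#'
#' @param wm A [build_weight_matrix()] result.
#' @param granularity Score lattice spacing (natural-log units);
#'   default `1e-3`.
#' @return An object of class `score_distribution` with `granularity`,
#'   `score_points` (ascending lattice scores), `prob` (point mass) and
#'   `tail_prob` (`P(score >= point)`, non-increasing, 1 at the minimum).
#' @export
score_pvalue_table <- function(wm, granularity = 1e-3) {
  stopifnot(inherits(wm, "weight_matrix"))
  if (granularity <= 0) stop("granularity must be positive")
  K <- round(wm$weights / granularity)
  mode(K) <- "integer"
  # Reject a lattice so coarse it erases real score differences.
  collapsed <- apply(K, 1, function(r) length(unique(r)) == 1L)
  varying <- apply(wm$weights, 1, function(r) diff(range(r)) > 1e-12)
  if (any(collapsed & varying) && all(collapsed))
    stop("granularity ", granularity,
         " collapses all weights to a single score point; use a finer value")
  p <- as.numeric(wm$background)
  dp <- 1
  lo <- 0L
  for (j in seq_len(nrow(K))) {
    kj <- K[j, ]
    lo2 <- lo + min(kj)
    hi2 <- lo + length(dp) - 1L + max(kj)
    new <- numeric(hi2 - lo2 + 1L)
    for (b in 1:4) {
      idx <- seq_along(dp) + (lo + kj[b] - lo2)
      new[idx] <- new[idx] + dp * p[b]
    }
    dp <- new
    lo <- lo2
  }
  tail <- rev(cumsum(rev(dp)))
  tail <- pmin(pmax(tail, 0), 1)
  structure(list(
    tf_name = wm$tf_name,
    width = nrow(K),
    granularity = granularity,
    score_points = (lo + seq_along(dp) - 1L) * granularity,
    prob = dp,
    tail_prob = tail
  ), class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  cat(sprintf(
    "score_distribution '%s': %d points in [%.3f, %.3f], granularity %g\n",
    x$tf_name, length(x$score_points), min(x$score_points),
    max(x$score_points), x$granularity))
  invisible(x)
}

#' P-value of a window score
#'
#' Tail probability `P(score >= s)` under the background, read from the
#' score lattice at the nearest point.
#'
#' @param dist A [score_pvalue_table()] result.
#' @param score Numeric vector of window scores.
#' @return P-values in (0, 1].
#' @export
motif_pvalue <- function(dist, score) {
  stopifnot(inherits(dist, "score_distribution"))
  idx <- round(score / dist$granularity) - round(dist$score_points[1] /
                                                   dist$granularity) + 1L
  idx <- pmin(pmax(idx, 1L), length(dist$tail_prob))
  dist$tail_prob[idx]
}

#' Scan threshold for a per-window p-value
#'
#' The smallest lattice score whose tail probability is at most `pvalue`.
#' Scanning i.i.d. background at this threshold yields a per-window
#' false-positive rate of at most `pvalue`.
#'
#' @param dist A [score_pvalue_table()] result.
#' @param pvalue Target per-window false-positive rate in (0, 1].
#' @return A score threshold. Lattice rounding can shift a true window
#'   score by up to `width * granularity / 2`, so the returned value is
#'   the selected lattice score minus that slack: every window whose
#'   rounded score meets the tail cutoff also passes on its exact score.
#'   If `pvalue` is below the smallest attainable tail probability, a
#'   value just above the maximum score is returned with a warning (no
#'   window can reach it).
#' @export
threshold_for_pvalue <- function(dist, pvalue) {
  stopifnot(inherits(dist, "score_distribution"))
  if (pvalue <= 0 || pvalue > 1) stop("pvalue must be in (0, 1]")
  slack <- dist$width * dist$granularity / 2
  # restrict to achievable scores (positive mass): the threshold should be
  # the weakest score a real window can attain at the requested rate, not
  # an empty lattice point between two atoms
  idx <- which(dist$tail_prob <= pvalue & dist$prob > 0)
  if (length(idx) == 0L) {
    warning("pvalue ", pvalue, " is below the smallest attainable tail ",
            "probability (", signif(min(dist$tail_prob), 3),
            "); returning a threshold above the maximum score")
    return(max(dist$score_points) + dist$granularity + slack)
  }
  dist$score_points[idx[1]] - slack
}
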