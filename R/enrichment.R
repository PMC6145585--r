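#' Background binding-site rate from accessible-chromatin sequence
#'
#' Scans a set of background sequences (e.g. accessible regions of the
#' blastoderm genome) on both strands at the given threshold and returns
#' the per-(position, strand) hit rate — the null expectation per scanned
#' window for an enhancer of identical composition.
#'
#' @param wm A [build_weight_matrix()] result.
#' @param threshold Scan score threshold.
#' @param background_sequences Named character vector of DNA sequences
#'   (as returned by [read_fasta()]).
#' @return An object of class `background_rate` with `tf_name`,
#'   `threshold`, `hits_per_position` and `positions_scanned`.
#' @export
estimate_background_rate <- function(wm, threshold, background_sequences) {
  stopifnot(inherits(wm, "weight_matrix"))
  if (length(background_sequences) == 0L)
    stop("background sequence set is empty")
  hits <- 0
  positions <- 0
  for (s in background_sequences) {
    ct <- .count_hits(wm, s, threshold)
    hits <- hits + ct$hits
    positions <- positions + ct$positions
  }
  if (positions < 1)
    stop("no scannable positions in the background set (sequences shorter ",
         "than the matrix width?)")
  structure(list(tf_name = wm$tf_name, threshold = threshold,
                 hits_per_position = hits / positions,
                 hits = hits, positions_scanned = positions),
            class = "background_rate")
}

#' Binding-site enrichment of an enhancer over the genomic background
#'
#' Compares the observed both-strand site count in an enhancer with the
#' expectation for a background region of identical size,
#' `expected = rate * 2 * (L - width + 1)`, and reports the signed score
#' `log2((observed + smoothing) / (expected + smoothing))`. Positive
#' scores indicate over-representation, negative under-representation.
#'
#' @param sequence Enhancer DNA string.
#' @param wm Weight matrix; must match the one used for `rate`.
#' @param threshold Scan threshold; must equal `rate$threshold`.
#' @param rate An [estimate_background_rate()] result.
#' @param smoothing Pseudo-count added to both counts; default 0.5.
#' @param enhancer_id Label carried into the result.
#' @return An object of class `enrichment_result` with `enhancer_id`,
#'   `tf_name`, `threshold`, `observed_count`, `expected_count`, `score`.
#' @export
compute_enrichment <- function(sequence, wm, threshold, rate,
                               smoothing = 0.5, enhancer_id = "enhancer") {
  stopifnot(inherits(wm, "weight_matrix"),
            inherits(rate, "background_rate"))
  if (!identical(rate$tf_name, wm$tf_name))
    stop("background rate was computed for '", rate$tf_name,
         "', not '", wm$tf_name, "'")
  if (abs(rate$threshold - threshold) > 1e-9)
    stop("background rate was computed at threshold ", rate$threshold,
         ", not ", threshold)
  ct <- .count_hits(wm, sequence, threshold)
  expected <- rate$hits_per_position * ct$positions
  structure(list(
    enhancer_id = enhancer_id, tf_name = wm$tf_name, threshold = threshold,
    observed_count = ct$hits, expected_count = expected,
    score = log2((ct$hits + smoothing) / (expected + smoothing))
  ), class = "enrichment_result")
}

#' Integer-threshold sensitivity scan for binding-site co-evolution
#'
#' The enrichment statistic depends on the score threshold that defines a
#' "site", which is hard to fix rigorously. This scan computes, at every
#' integer threshold from 1 up to the larger of the two matrices' maximum
#' scores, the per-ortholog enrichment of both factors and the Spearman
#' correlation of the two enrichment vectors across orthologs — a
#' sensitivity analysis for the threshold choice. Thresholds at which
#' either enrichment vector has fewer than three distinct values yield an
#' undefined correlation, recorded with a reason rather than dropped.
#'
#' @param orthologs Named character vector of orthologous enhancer
#'   sequences, one per species (at least 4).
#' @param wm_a,wm_b Weight matrices for the two factors.
#' @param background_sequences Background set for the null rate.
#' @param smoothing Enrichment pseudo-count; default 0.5.
#' @return An object of class `coevolution_result`: `tf_pair`,
#'   `thresholds`, `rho`, `pvalue`, `reason` (NA where rho is defined),
#'   and `enrichment` — a long data.frame (ortholog_id, tf_name,
#'   threshold, observed, expected, score).
#' @export
threshold_sensitivity_scan <- function(orthologs, wm_a, wm_b,
                                       background_sequences,
                                       smoothing = 0.5) {
  stopifnot(inherits(wm_a, "weight_matrix"),
            inherits(wm_b, "weight_matrix"))
  if (length(orthologs) < 4L)
    stop("need at least 4 ortholog sequences, got ", length(orthologs))
  if (is.null(names(orthologs)))
    names(orthologs) <- paste0("ortholog_", seq_along(orthologs))
  thresholds <- seq_len(max(1, floor(max(wm_a$max_score, wm_b$max_score))))

  per_tf <- lapply(list(wm_a, wm_b), function(wm) {
    bg <- unlist(lapply(background_sequences, .all_window_scores, wm = wm))
    bg <- bg[!is.na(bg)]
    orth <- lapply(orthologs, .all_window_scores, wm = wm)
    list(wm = wm, bg = bg, orth = orth)
  })

  rows <- list()
  rho <- pval <- rep(NA_real_, length(thresholds))
  reason <- rep(NA_character_, length(thresholds))
  scores_at <- function(tf, t) {
    rate <- sum(tf$bg >= t) / length(tf$bg)
    vapply(tf$orth, function(sc) {
      ok <- !is.na(sc)
      obs <- sum(sc[ok] >= t)
      log2((obs + smoothing) / (rate * sum(ok) + smoothing))
    }, numeric(1))
  }
  for (i in seq_along(thresholds)) {
    t <- thresholds[i]
    ea <- scores_at(per_tf[[1]], t)
    eb <- scores_at(per_tf[[2]], t)
    for (tf_i in 1:2) {
      e <- if (tf_i == 1) ea else eb
      rows[[length(rows) + 1L]] <- data.frame(
        ortholog_id = names(orthologs),
        tf_name = per_tf[[tf_i]]$wm$tf_name,
        threshold = t, score = e, row.names = NULL,
        stringsAsFactors = FALSE)
    }
    if (length(unique(ea)) < 3L || length(unique(eb)) < 3L) {
      reason[i] <- "constant_enrichment"
    } else {
      sp <- spearman_correlation(ea, eb)
      if (is.na(sp$rho)) {
        reason[i] <- sp$reason
      } else {
        rho[i] <- sp$rho
        pval[i] <- sp$pvalue
      }
    }
  }
  structure(list(
    tf_pair = c(wm_a$tf_name, wm_b$tf_name),
    thresholds = thresholds, rho = rho, pvalue = pval, reason = reason,
    enrichment = do.call(rbind, rows)
  ), class = "coevolution_result")
}

#' @export
print.coevolution_result <- function(x, ...) {
  cat(sprintf("coevolution_result %s vs %s: %d thresholds, %d with ",
              x$tf_pair[1], x$tf_pair[2], length(x$thresholds),
              sum(!is.na(x$rho))), "defined rho\n")
  invisible(x)
}

# All n! permutations of 1..n as an (n!, n) integer matrix.
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Spearman rank correlation with exact small-sample p-values
#'
#' Rho is the Pearson correlation of mid-ranks (ties receive average
#' ranks). The two-sided p-value is exact — computed by enumerating all
#' `n!` permutations of one vector — for `n <= 9`, and a t-approximation
#' with `n - 2` degrees of freedom otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list with `rho`, `pvalue`, `n`, `method` and `reason`
#'   (`NA` unless rho is undefined, e.g. `"constant_input"`).
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(list(rho = NA_real_, pvalue = NA_real_, n = n,
                method = "undefined", reason = "constant_input"))
  }
  rho <- cor(rx, ry)
  if (n <= 9L) {
    perms <- .permutations(n)
    ym <- matrix(ry[perms], nrow = nrow(perms))
    cross <- as.vector(ym %*% rx)
    denom <- (n - 1) * sd(rx) * sd(ry)
    rho_all <- (cross - n * mean(rx) * mean(ry)) / denom
    pvalue <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    pvalue <- min(1, 2 * pt(-abs(tt), df = n - 2))
    method <- "t_approximation"
  }
  list(rho = rho, pvalue = pvalue, n = n, method = method,
       reason = NA_character_)
}
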