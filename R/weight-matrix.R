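#' Background base-composition model
#'
#' A background model holds the genomic base frequencies against which
#' log-odds weights and score-distribution p-values are computed. The
#' default is uniform (0.25 per base); pass GC content via [gc_background()]
#' when the sequence composition is known.
#'
#' @param frequencies Numeric vector of length 4 with probabilities for
#'   A, C, G, T (in that order). Must be strictly positive and sum to 1
#'   within `1e-9`.
#' @return An object of class `background_model`: a named numeric vector.
#' @examples
#' background_model()                   # uniform
#' background_model(c(.3, .2, .2, .3)) # AT-rich
#' @export
background_model <- function(frequencies = rep(0.25, 4)) {
  frequencies <- as.numeric(frequencies)
  if (length(frequencies) != 4L)
    stop("background model needs exactly 4 base frequencies (A,C,G,T)")
  if (any(frequencies <= 0))
    stop("background frequencies must be strictly positive")
  if (abs(sum(frequencies) - 1) > 1e-9)
    stop("background frequencies must sum to 1 (got ", sum(frequencies), ")")
  structure(setNames(frequencies, DNA_BASES), class = "background_model")
}

#' @rdname background_model
#' @param gc_content GC fraction in (0, 1); A/T and C/G are split equally.
#' @export
gc_background <- function(gc_content) {
  if (gc_content <= 0 || gc_content >= 1)
    stop("gc_content must be in (0, 1)")
  background_model(c((1 - gc_content) / 2, gc_content / 2,
                     gc_content / 2, (1 - gc_content) / 2))
}

#' Construct a count matrix for a transcription factor
#'
#' Raw per-position base counts, the form in which published binding
#' preferences are distributed. Converted to log-odds weights with
#' [build_weight_matrix()].
#'
#' @param tf_name Factor label (e.g. `"Hb"`, `"Cad"`).
#' @param counts Numeric matrix, width x 4, columns ordered A, C, G, T.
#'   Non-negative; every position must have at least one positive count.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(tf_name, counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L)
    stop("counts must have 4 columns (A,C,G,T); got ", ncol(counts))
  if (nrow(counts) < 1L)
    stop("count matrix must have width >= 1")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  if (any(rowSums(counts) <= 0))
    stop("every matrix position needs at least one positive count ",
         "(all-zero position at ",
         paste(which(rowSums(counts) <= 0), collapse = ", "), ")")
  colnames(counts) <- DNA_BASES
  structure(list(tf_name = as.character(tf_name), counts = counts),
            class = "count_matrix")
}

#' Build a log-odds weight matrix from a count matrix
#'
#' Converts counts to frequencies with a pseudocount apportioned in
#' proportion to the background frequencies (PATSER behaviour), then to
#' natural-log odds against the background:
#' \deqn{w_{ib} = \ln\frac{(c_{ib} + s\,p_b)/(N_i + s)}{p_b}}
#' where \eqn{c_{ib}} is the count for base \eqn{b} at position \eqn{i},
#' \eqn{N_i} the position total, \eqn{s} the pseudocount and \eqn{p_b} the
#' background frequency. The default pseudocount is 1, the value used when
#' preparing count matrices for PATSER.
#'
#' @param counts A [count_matrix()].
#' @param pseudocount Non-negative smoothing mass; default 1. Zero is only
#'   allowed when every count is positive.
#' @param background A [background_model()]; default uniform.
#' @return An object of class `weight_matrix` with elements `tf_name`,
#'   `weights` (width x 4 log-odds), `pseudocount`, `background`,
#'   `min_score`, `max_score`.
#' @examples
#' cm <- count_matrix("toy", matrix(c(8, 0, 0, 0), 1, 4))
#' wm <- build_weight_matrix(cm)
#' wm$max_score  # ln((8.25/9)/0.25)
#' @export
build_weight_matrix <- function(counts, pseudocount = 1,
                                background = background_model()) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!inherits(background, "background_model"))
    background <- background_model(background)
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (pseudocount == 0 && any(counts$counts == 0))
    stop("pseudocount 0 with a zero count would give -Inf weights")
  cm <- counts$counts
  totals <- rowSums(cm)
  p <- as.numeric(background)
  freqs <- sweep(cm, 2, pseudocount * p, "+") / (totals + pseudocount)
  weights <- log(sweep(freqs, 2, p, "/"))
  colnames(weights) <- DNA_BASES
  structure(list(
    tf_name = counts$tf_name,
    weights = weights,
    pseudocount = pseudocount,
    background = background,
    min_score = sum(apply(weights, 1, min)),
    max_score = sum(apply(weights, 1, max))
  ), class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("weight_matrix '%s': width %d, score range [%.3f, %.3f]\n",
              x$tf_name, nrow(x$weights), x$min_score, x$max_score))
  invisible(x)
}

#' Width (positions) of a weight matrix
#' @param wm A `weight_matrix`.
#' @return Integer width.
#' @export
motif_width <- function(wm) nrow(wm$weights)

#' Consensus sequence of a weight matrix
#'
#' The base with the largest weight at each position (ties broken in
#' A,C,G,T order). Scoring the consensus returns `max_score`.
#' @param wm A `weight_matrix`.
#' @return Character string of the matrix width.
#' @export
consensus_sequence <- function(wm) {
  paste(DNA_BASES[apply(wm$weights, 1, which.max)], collapse = "")
}

# Frequencies implied by the weights: f_ib = p_b * exp(w_ib).
.implied_frequencies <- function(wm) {
  f <- sweep(exp(wm$weights), 2, as.numeric(wm$background), "*")
  f / rowSums(f)  # guard rounding
}

#' Per-position information content (bits)
#'
#' `2 + sum_b f log2 f` of the pseudocount-smoothed frequencies; used to
#' rank positions when designing knockout mutations.
#' @param wm A `weight_matrix`.
#' @return Numeric vector, one value per position.
#' @export
information_content <- function(wm) {
  f <- .implied_frequencies(wm)
  2 + rowSums(ifelse(f > 0, f * log2(f), 0))
}
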