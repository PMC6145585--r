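# Window scores for an encoded sequence under a weight matrix.
# Returns one score per start (1-based); windows containing N score NA.
.window_scores <- function(codes, weights) {
  w <- nrow(weights)
  n <- length(codes) - w + 1L
  if (n < 1L) return(numeric(0))
  scores <- numeric(n)
  for (j in seq_len(w)) {
    scores <- scores + weights[j, ][codes[j:(j + n - 1L)]]
  }
  scores
}

#' Scan a sequence for binding sites
#'
#' Scores every window of `sequence` on the requested strands with the
#' log-odds weight matrix and reports windows scoring at or above
#' `threshold`. The reverse-strand score of a window is the forward score
#' of its reverse complement; reverse-strand hits are reported in forward
#' coordinates. Windows containing `N` are skipped. Overlapping hits are
#' all reported.
#'
#' @param wm A [build_weight_matrix()] result.
#' @param sequence DNA string over A,C,G,T,N (case-insensitive).
#' @param threshold Minimum window score for a hit.
#' @param strands `"both"` (default) or `"forward"`.
#' @param sequence_id Identifier recorded in the hit table.
#' @param dist Optional [score_pvalue_table()] result used to annotate each
#'   hit with a p-value; otherwise `pvalue` is `NA`.
#' @return A `data.frame` of hits with columns `tf_name`, `sequence_id`,
#'   `start` (0-based), `end` (exclusive, `start + width`), `strand`
#'   (`"+"`/`"-"`), `score`, `pvalue`; sorted by `start` then strand.
#'   Sequences shorter than the matrix width give zero rows.
#' @examples
#' cm <- count_matrix("AA", matrix(c(9, 9, 0, 0, 0, 0, 0, 0), 2, 4))
#' wm <- build_weight_matrix(cm)
#' scan_sequence(wm, "AAAA", threshold = wm$max_score, strands = "forward")
#' @export
scan_sequence <- function(wm, sequence, threshold,
                          strands = c("both", "forward"),
                          sequence_id = "seq", dist = NULL) {
  stopifnot(inherits(wm, "weight_matrix"))
  strands <- match.arg(strands)
  sequence <- toupper(sequence)
  w <- motif_width(wm)
  L <- nchar(sequence)
  empty <- data.frame(
    tf_name = character(0), sequence_id = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    score = numeric(0), pvalue = numeric(0), stringsAsFactors = FALSE)
  if (L < w) return(empty)

  codes <- .encode_dna(sequence)
  fwd <- .window_scores(codes, wm$weights)
  starts0 <- seq_along(fwd) - 1L
  hits <- list()
  keep <- !is.na(fwd) & fwd >= threshold
  if (any(keep)) {
    hits[["+"]] <- data.frame(start = starts0[keep], strand = "+",
                              score = fwd[keep], stringsAsFactors = FALSE)
  }
  if (strands == "both") {
    rc_codes <- .encode_dna(.revcomp(sequence))
    rev <- .window_scores(rc_codes, wm$weights)
    # window starting at 0-based s' of the reverse complement covers
    # forward positions [L - w - s', L - s')
    rstarts0 <- L - w - (seq_along(rev) - 1L)
    keep <- !is.na(rev) & rev >= threshold
    if (any(keep)) {
      hits[["-"]] <- data.frame(start = rstarts0[keep], strand = "-",
                                score = rev[keep], stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
  data.frame(
    tf_name = wm$tf_name, sequence_id = sequence_id,
    start = out$start, end = out$start + w, strand = out$strand,
    score = out$score,
    pvalue = if (is.null(dist)) NA_real_ else motif_pvalue(dist, out$score),
    row.names = NULL, stringsAsFactors = FALSE)
}

# Count both-strand hits and scannable (position, strand) pairs without
# materialising the hit table; used by the enrichment module.
.count_hits <- function(wm, sequence, threshold) {
  sequence <- toupper(sequence)
  codes <- .encode_dna(sequence)
  fwd <- .window_scores(codes, wm$weights)
  rev <- .window_scores(.encode_dna(.revcomp(sequence)), wm$weights)
  scores <- c(fwd, rev)
  ok <- !is.na(scores)
  list(hits = sum(scores[ok] >= threshold), positions = sum(ok))
}

# Both-strand window scores concatenated (NA for N windows); lets the
# sensitivity scan count hits at many thresholds from one pass.
.all_window_scores <- function(wm, sequence) {
  sequence <- toupper(sequence)
  c(.window_scores(.encode_dna(sequence), wm$weights),
    .window_scores(.encode_dna(.revcomp(sequence)), wm$weights))
}
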