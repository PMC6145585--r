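# Independent oracles and fixture builders. These deliberately avoid the
# package's internal code paths (string-by-string scoring, exhaustive
# k-mer enumeration, brute-force permutation), so agreement is evidence
# of correctness rather than of shared bugs.

ORACLE_BASES <- c("A", "C", "G", "T")
ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(s) {
  paste(rev(ORACLE_COMP[strsplit(s, "")[[1]]]), collapse = "")
}

# Score of one window by direct per-character lookup; NA if any N.
oracle_window_score <- function(wm, window) {
  chars <- strsplit(window, "")[[1]]
  if (any(!chars %in% ORACLE_BASES)) return(NA_real_)
  sum(vapply(seq_along(chars),
             function(j) wm$weights[j, chars[j]], numeric(1)))
}

# All-window scan on both strands by explicit loops.
oracle_scan <- function(wm, sequence, threshold, strands = "both") {
  w <- nrow(wm$weights)
  L <- nchar(sequence)
  rows <- list()
  for (start0 in seq_len(max(L - w + 1L, 0L)) - 1L) {
    win <- substr(sequence, start0 + 1L, start0 + w)
    sc <- oracle_window_score(wm, win)
    if (!is.na(sc) && sc >= threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        start = start0, strand = "+", score = sc)
    if (strands == "both") {
      sc <- oracle_window_score(wm, oracle_revcomp(win))
      if (!is.na(sc) && sc >= threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          start = start0, strand = "-", score = sc)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
}

# Exact tail probabilities by enumerating all 4^width windows with
# weights rounded to the same lattice the package uses.
oracle_tail_table <- function(wm, granularity) {
  w <- nrow(wm$weights)
  p <- as.numeric(wm$background)
  K <- round(wm$weights / granularity)
  grids <- expand.grid(rep(list(1:4), w))
  scores <- numeric(nrow(grids))
  probs <- rep(1, nrow(grids))
  for (j in seq_len(w)) {
    scores <- scores + K[j, grids[[j]]]
    probs <- probs * p[grids[[j]]]
  }
  agg <- tapply(probs, scores, sum)
  pts <- as.numeric(names(agg))
  o <- order(pts)
  list(score_points = pts[o] * granularity,
       prob = as.numeric(agg)[o],
       tail_prob = rev(cumsum(rev(as.numeric(agg)[o]))))
}

# All permutations of 1..n, built by position-wise insertion (a different
# construction from the package's recursive generator).
oracle_permutations <- function(n) {
  out <- matrix(1L, 1L, 1L)
  for (k in 2:n) {
    grown <- vector("list", k)
    for (pos in seq_len(k)) {
      grown[[pos]] <- cbind(out[, seq_len(pos - 1L), drop = FALSE], k,
                            out[, seq(pos, k - 1L)[seq_len(k - pos)],
                                drop = FALSE])
    }
    out <- do.call(rbind, grown)
  }
  unname(out)
}

# Two-sided exact Spearman p by brute-force permutation, rho via R's own
# cor(method = "spearman").
oracle_spearman_exact <- function(x, y) {
  n <- length(x)
  rho <- cor(x, y, method = "spearman")
  perms <- oracle_permutations(n)
  rhos <- apply(perms, 1, function(pm) cor(x, y[pm], method = "spearman"))
  list(rho = rho, pvalue = mean(abs(rhos) >= abs(rho) - 1e-12))
}

# A random count matrix with at least one positive count per position.
rand_count_matrix <- function(width, tf_name = "rand") {
  repeat {
    counts <- matrix(rpois(width * 4, 3), width, 4)
    if (all(rowSums(counts) > 0)) break
  }
  count_matrix(tf_name, counts)
}

# Random DNA string, optionally salted with N.
rand_dna <- function(length, n_prob = 0) {
  alph <- if (n_prob > 0) c(ORACLE_BASES, "N") else ORACLE_BASES
  prob <- if (n_prob > 0) c(rep((1 - n_prob) / 4, 4), n_prob) else NULL
  paste(sample(alph, length, replace = TRUE, prob = prob), collapse = "")
}

# Weight matrix whose consensus is `consensus` with a dominant count
# `strength` there and 0 elsewhere (pseudocount keeps weights finite).
consensus_wm <- function(tf_name, consensus, strength = 20) {
  chars <- strsplit(consensus, "")[[1]]
  counts <- matrix(0, length(chars), 4)
  counts[cbind(seq_along(chars), match(chars, ORACLE_BASES))] <- strength
  build_weight_matrix(count_matrix(tf_name, counts))
}
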