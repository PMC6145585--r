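# A <-> G are purines, C <-> T pyrimidines; an edit crossing the two
# classes is a transversion. Transversions are preferred when designing
# knockouts because they move the score furthest for typical matrices.
.is_transversion <- function(old, new) {
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  purine[old] != purine[new]
}

# Hits of one weight matrix restricted to a forward-coordinate region
# [from0, to0) of `sequence`; used to test whether an edit disturbs
# protected sites near the edited window.
.hits_in_region <- function(wm, sequence, threshold, from0, to0) {
  from0 <- max(from0, 0L)
  to0 <- min(to0, nchar(sequence))
  if (to0 - from0 < motif_width(wm)) {
    return(data.frame(start = integer(0), strand = character(0)))
  }
  sub <- substr(sequence, from0 + 1L, to0)
  h <- scan_sequence(wm, sub, threshold, strands = "both")
  # identity is (position, strand): an edit is damaging if it creates or
  # destroys a protected hit, not if it merely shifts a surviving hit's
  # score
  data.frame(start = h$start + from0, strand = h$strand,
             stringsAsFactors = FALSE)
}

# Score of the specific (start0, strand) window of `sequence` under wm.
.window_score_at <- function(wm, sequence, start0, strand) {
  w <- motif_width(wm)
  win <- substr(sequence, start0 + 1L, start0 + w)
  if (strand == "-") win <- .revcomp(win)
  sum(.window_scores(.encode_dna(win), wm$weights))
}

#' Design binding-site knockout mutations
#'
#' Greedily mutates every predicted site of a target factor below its scan
#' threshold while protecting the predicted sites of other factors. For
#' each target hit, candidate single-base edits are tried at positions
#' ordered by the target matrix's information content; an edit is
#' admissible only if it neither creates nor destroys any protected-factor
#' hit (at that factor's own p-value threshold) in the neighbourhood of the
#' edit. Among admissible edits the one minimising the rescored target
#' window is applied (ties: prefer transversions, then the smaller
#' position, then A,C,G,T order of the new base). A site with no
#' admissible path below threshold is left unmutated and flagged — the
#' low-affinity-site escape hatch that keeps overlapping sites intact.
#'
#' @param sequence DNA string (A,C,G,T,N).
#' @param target_wm Weight matrix of the factor whose sites are removed.
#' @param protected_wms List of weight matrices whose sites must not
#'   change. All matrices must share the target's background model.
#' @param pvalue_cutoff Per-window p-value defining a "site" for both the
#'   target and the protected factors; default 0.003.
#' @param max_edits_per_site Maximum base changes per target site;
#'   must be positive when any site is present.
#' @param granularity Score lattice spacing for the p-value tables.
#' @return An object of class `mutation_plan`: `original_sequence`,
#'   `mutated_sequence` (same length), `edits` (data.frame of 0-based
#'   `position`, `old`, `new`), `abolished_hits`, `unmutated_sites`
#'   (flagged target hits with a reason), and `collateral_report`
#'   (per-factor hit counts before/after, target first).
#' @export
design_knockout_mutations <- function(sequence, target_wm,
                                      protected_wms = list(),
                                      pvalue_cutoff = 0.003,
                                      max_edits_per_site = 3,
                                      granularity = 1e-3) {
  stopifnot(inherits(target_wm, "weight_matrix"))
  sequence <- toupper(sequence)
  for (pw in protected_wms) {
    if (!isTRUE(all.equal(as.numeric(pw$background),
                          as.numeric(target_wm$background))))
      stop("all matrices must share the target's background model")
  }
  t_dist <- score_pvalue_table(target_wm, granularity)
  t_thr <- threshold_for_pvalue(t_dist, pvalue_cutoff)
  p_thr <- vapply(protected_wms, function(pw)
    threshold_for_pvalue(score_pvalue_table(pw, granularity), pvalue_cutoff),
    numeric(1))

  target_hits <- scan_sequence(target_wm, sequence, t_thr, dist = t_dist)
  if (nrow(target_hits) > 0L && max_edits_per_site <= 0)
    stop("max_edits_per_site must be positive when target sites are present")

  before <- lapply(seq_along(protected_wms), function(i)
    scan_sequence(protected_wms[[i]], sequence, p_thr[i]))

  w <- motif_width(target_wm)
  maxpw <- if (length(protected_wms)) {
    max(vapply(protected_wms, motif_width, integer(1)))
  } else 0L
  ic <- information_content(target_wm)
  current <- sequence
  edits <- list()
  unmutated <- list()

  for (k in seq_len(nrow(target_hits))) {
    hit <- target_hits[k, ]
    # earlier edits may already have taken this window below threshold
    if (.window_score_at(target_wm, current, hit$start, hit$strand) < t_thr)
      next
    # forward positions of the window, ranked by matrix information
    # content (matrix column j reads forward position start+j on '+',
    # end-j+1 complemented on '-')
    pos0 <- hit$start + seq_len(w) - 1L
    col_of_pos <- if (hit$strand == "+") seq_len(w) else rev(seq_len(w))
    pos_order <- pos0[order(-ic[col_of_pos], pos0)]
    region <- c(hit$start - maxpw + 1L, hit$end + maxpw - 1L)

    site_seq <- current
    site_edits <- list()
    conflicted <- FALSE
    for (step in seq_len(max_edits_per_site)) {
      base_score <- .window_score_at(target_wm, site_seq, hit$start,
                                     hit$strand)
      if (base_score < t_thr) break
      prot_ref <- lapply(seq_along(protected_wms), function(i)
        .hits_in_region(protected_wms[[i]], site_seq, p_thr[i],
                        region[1], region[2]))
      best <- NULL
      for (p0 in pos_order) {
        old <- substr(site_seq, p0 + 1L, p0 + 1L)
        if (!(old %in% DNA_BASES)) next
        for (new in setdiff(DNA_BASES, old)) {
          cand <- site_seq
          substr(cand, p0 + 1L, p0 + 1L) <- new
          sc <- .window_score_at(target_wm, cand, hit$start, hit$strand)
          if (sc >= base_score) next  # must strictly lower the site score
          ok <- TRUE
          for (i in seq_along(protected_wms)) {
            after_i <- .hits_in_region(protected_wms[[i]], cand, p_thr[i],
                                       region[1], region[2])
            if (!identical(prot_ref[[i]], after_i)) { ok <- FALSE; break }
          }
          if (!ok) next
          tv <- .is_transversion(old, new)
          if (is.null(best) || sc < best$score - 1e-12 ||
              (abs(sc - best$score) <= 1e-12 && tv && !best$tv)) {
            best <- list(pos0 = p0, old = old, new = new, score = sc,
                         tv = tv)
          }
        }
      }
      if (is.null(best)) { conflicted <- TRUE; break }
      substr(site_seq, best$pos0 + 1L, best$pos0 + 1L) <- best$new
      site_edits[[length(site_edits) + 1L]] <-
        data.frame(position = best$pos0, old = best$old, new = best$new,
                   stringsAsFactors = FALSE)
    }
    final_score <- .window_score_at(target_wm, site_seq, hit$start,
                                    hit$strand)
    if (final_score < t_thr) {
      current <- site_seq
      edits <- c(edits, site_edits)
    } else {
      reason <- if (conflicted) "protected_conflict" else "max_edits_reached"
      unmutated[[length(unmutated) + 1L]] <-
        cbind(hit, reason = reason, row.names = NULL)
    }
  }

  after_target <- scan_sequence(target_wm, current, t_thr, dist = t_dist)
  after <- lapply(seq_along(protected_wms), function(i)
    scan_sequence(protected_wms[[i]], current, p_thr[i]))
  key <- function(h) paste(h$start, h$strand)
  abolished <- target_hits[!(key(target_hits) %in% key(after_target)), ,
                           drop = FALSE]
  collateral <- data.frame(
    tf_name = c(target_wm$tf_name,
                vapply(protected_wms, `[[`, character(1), "tf_name")),
    role = c("target", rep("protected", length(protected_wms))),
    hits_before = c(nrow(target_hits),
                    vapply(before, nrow, integer(1))),
    hits_after = c(nrow(after_target), vapply(after, nrow, integer(1))),
    stringsAsFactors = FALSE)

  structure(list(
    original_sequence = sequence,
    mutated_sequence = current,
    edits = if (length(edits)) do.call(rbind, edits) else
      data.frame(position = integer(0), old = character(0),
                 new = character(0), stringsAsFactors = FALSE),
    abolished_hits = abolished,
    unmutated_sites = if (length(unmutated)) do.call(rbind, unmutated) else
      target_hits[0, ],
    remaining_hits = after_target,
    collateral_report = collateral,
    threshold = t_thr,
    pvalue_cutoff = pvalue_cutoff
  ), class = "mutation_plan")
}

#' @export
print.mutation_plan <- function(x, ...) {
  cat(sprintf(
    "mutation_plan: %d edits, %d sites abolished, %d left unmutated\n",
    nrow(x$edits), nrow(x$abolished_hits), nrow(x$unmutated_sites)))
  print(x$collateral_report)
  invisible(x)
}
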