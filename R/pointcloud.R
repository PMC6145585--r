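#' Cellular-resolution expression pointcloud for one embryo
#'
#' One row per nucleus: position along the anterior-posterior axis (`ap`,
#' fraction, 0 = anterior) and around the dorsal-ventral circumference
#' (`dv`, fraction in `[0, 1)`, 0 = dorsal midline, 0.5 = ventral
#' midline), plus one named intensity column per expression channel
#' (e.g. `lacZ`, `hkb`).
#'
#' @param embryo_id Embryo identifier.
#' @param genotype Genotype label, e.g. `"wild_type"` or `"sna_hb"`.
#' @param timepoint Developmental timepoint, integer 1-6 (membrane
#'   invagination stages).
#' @param nuclei A data.frame with columns `ap`, `dv` and at least one
#'   channel column of finite non-negative intensities.
#' @return An object of class `pointcloud`.
#' @export
pointcloud <- function(embryo_id, genotype, timepoint, nuclei) {
  nuclei <- as.data.frame(nuclei)
  if (nrow(nuclei) < 1L) stop("pointcloud needs at least one nucleus")
  if (!all(c("ap", "dv") %in% names(nuclei)))
    stop("nuclei must have 'ap' and 'dv' columns")
  channels <- setdiff(names(nuclei), c("ap", "dv"))
  if (length(channels) == 0L)
    stop("pointcloud needs at least one channel column")
  timepoint <- as.integer(timepoint)
  if (is.na(timepoint) || timepoint < 1L || timepoint > 6L)
    stop("timepoint must be an integer in 1..6")
  bad <- which(nuclei$ap < 0 | nuclei$ap > 1 | !is.finite(nuclei$ap))
  if (length(bad))
    stop("embryo ", embryo_id, ": ap out of [0,1] at row ",
         paste(head(bad, 5), collapse = ", "))
  bad <- which(nuclei$dv < 0 | nuclei$dv >= 1 | !is.finite(nuclei$dv))
  if (length(bad))
    stop("embryo ", embryo_id, ": dv out of [0,1) at row ",
         paste(head(bad, 5), collapse = ", "))
  for (ch in channels) {
    v <- nuclei[[ch]]
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad))
      stop("embryo ", embryo_id, ": channel '", ch,
           "' has negative or non-finite values at row ",
           paste(head(bad, 5), collapse = ", "))
  }
  structure(list(embryo_id = as.character(embryo_id),
                 genotype = as.character(genotype),
                 timepoint = timepoint,
                 nuclei = nuclei, channels = channels),
            class = "pointcloud")
}

#' @export
print.pointcloud <- function(x, ...) {
  cat(sprintf("pointcloud '%s' (%s, t%d): %d nuclei, channels %s\n",
              x$embryo_id, x$genotype, x$timepoint, nrow(x$nuclei),
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Dorsal-ventral strip definition for line traces
#'
#' A strip selects nuclei whose `dv` coordinate falls in any of the given
#' windows; their intensities are then averaged in `n_ap_bins` equal bins
#' along the anterior-posterior axis. Windows are half-open `[lo, hi)`
#' fractions of the circumference and may wrap past 1 (`lo > hi`).
#'
#' @param name Strip label.
#' @param dv_windows List of length-2 numeric vectors `c(lo, hi)`.
#' @param n_ap_bins Number of AP bins (>= 10); default 100.
#' @return An object of class `strip_spec`.
#' @export
strip_spec <- function(name, dv_windows, n_ap_bins = 100L) {
  if (length(dv_windows) == 0L) stop("at least one dv window is required")
  for (wn in dv_windows) {
    if (length(wn) != 2L || any(wn < 0) || any(wn >= 1))
      stop("each dv window must be c(lo, hi) with values in [0, 1)")
  }
  n_ap_bins <- as.integer(n_ap_bins)
  if (n_ap_bins < 10L) stop("n_ap_bins must be >= 10")
  structure(list(name = name, dv_windows = dv_windows,
                 n_ap_bins = n_ap_bins), class = "strip_spec")
}

#' @rdname strip_spec
#' @details `lateral_strip()` covers both left and right lateral bands
#'   (`[0.20, 0.30)` and `[0.70, 0.80)` of the circumference),
#'   `ventral_strip()` the ventral band `[0.45, 0.55)` around the ventral
#'   midline, and `full_strip()` the whole circumference. The embryo
#'   surface is symmetric in expectation about the ventral midline, so the
#'   two lateral bands are pooled.
#' @export
lateral_strip <- function(n_ap_bins = 100L) {
  strip_spec("lateral", list(c(0.20, 0.30), c(0.70, 0.80)), n_ap_bins)
}

#' @rdname strip_spec
#' @export
ventral_strip <- function(n_ap_bins = 100L) {
  strip_spec("ventral", list(c(0.45, 0.55)), n_ap_bins)
}

#' @rdname strip_spec
#' @export
full_strip <- function(n_ap_bins = 100L) {
  strip_spec("full", list(c(0, 0.999999)), n_ap_bins)
}

# Logical selector for nuclei inside a strip's dv windows (wrap-aware).
.in_strip <- function(dv, strip) {
  sel <- rep(FALSE, length(dv))
  for (wn in strip$dv_windows) {
    if (wn[1] <= wn[2]) {
      sel <- sel | (dv >= wn[1] & dv < wn[2])
    } else {
      sel <- sel | (dv >= wn[1] | dv < wn[2])
    }
  }
  sel
}

#' Default stripe search windows (AP fractions)
#'
#' Anterior-posterior windows within which each stripe's peak is sought.
#' These defaults bracket the stripe positions of the synthetic embryo
#' generator; for real data supply windows matched to the enhancer.
#' @return Named list of `c(lo, hi)` AP windows for stripes 2, 3 and 7.
#' @export
default_stripe_windows <- function() {
  list(`2` = c(0.33, 0.47), `3` = c(0.42, 0.55), `7` = c(0.78, 0.92))
}
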