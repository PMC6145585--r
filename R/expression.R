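#' Average a channel along the AP axis within a DV strip
#'
#' Nuclei inside the strip's DV windows are binned into equal AP bins and
#' the per-bin arithmetic mean intensity forms the line trace. Optionally
#' the trace is normalized to its maximum (bins without nuclei are
#' missing and excluded from the maximum).
#'
#' @param pc A [pointcloud()].
#' @param channel Channel name.
#' @param strip A [strip_spec()].
#' @param normalization `"none"` (default) or `"max"`.
#' @return An object of class `strip_trace`: `embryo_id`, `strip`,
#'   `ap_bin_centers`, `mean_intensity` (NA for empty bins),
#'   `normalization`.
#' @export
extract_strip_trace <- function(pc, channel, strip,
                                normalization = c("none", "max")) {
  stopifnot(inherits(pc, "pointcloud"), inherits(strip, "strip_spec"))
  normalization <- match.arg(normalization)
  if (!channel %in% pc$channels)
    stop("embryo ", pc$embryo_id, ": no channel '", channel,
         "' (have ", paste(pc$channels, collapse = ", "), ")")
  sel <- .in_strip(pc$nuclei$dv, strip)
  if (!any(sel))
    stop("embryo ", pc$embryo_id, ": no nuclei in strip '", strip$name, "'")
  ap <- pc$nuclei$ap[sel]
  val <- pc$nuclei[[channel]][sel]
  n <- strip$n_ap_bins
  idx <- pmin(pmax(floor(ap * n) + 1L, 1L), n)
  sums <- tapply(val, factor(idx, levels = seq_len(n)), mean)
  trace <- as.numeric(sums)
  centers <- (seq_len(n) - 0.5) / n
  if (normalization == "max") {
    m <- max(trace, na.rm = TRUE)
    if (!is.finite(m) || m <= 0)
      stop("embryo ", pc$embryo_id, ": channel '", channel,
           "' is all zero in strip '", strip$name,
           "'; cannot max-normalize")
    trace <- trace / m
  }
  structure(list(embryo_id = pc$embryo_id, strip = strip$name,
                 ap_bin_centers = centers, mean_intensity = trace,
                 normalization = normalization),
            class = "strip_trace")
}

# Missing-aware moving average of odd width (width 1 = no smoothing).
.smooth_trace <- function(v, width) {
  if (width <= 1L) return(v)
  half <- (width - 1L) %/% 2L
  n <- length(v)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    wnd <- v[max(1L, i - half):min(n, i + half)]
    if (any(!is.na(wnd))) out[i] <- mean(wnd, na.rm = TRUE)
  }
  out
}

#' Extract stripe peaks from a line trace
#'
#' Within each stripe's AP search window, the trace is lightly smoothed
#' (moving average) and the largest interior local maximum is located.
#' The reported level is read from the unsmoothed trace at that bin by
#' default (`level_from = "raw"`), so smoothing steadies the peak
#' position without attenuating its height; set `level_from =
#' "smoothed"` to report the smoothed value instead. If the window
#' contains no interior local maximum (e.g. a flat or monotone trace)
#' the window maximum is returned with `boundary = TRUE`. Windows with
#' only missing bins yield a missing peak.
#'
#' @param trace A [extract_strip_trace()] result.
#' @param stripe_windows Named list of `c(ap_lo, ap_hi)` windows, e.g.
#'   [default_stripe_windows()]. Windows must not overlap... they may
#'   share edges; peaks are searched independently per window.
#' @param smooth_width Moving-average width in bins (odd); default 3.
#' @param level_from Report peak levels from the `"raw"` (default) or
#'   `"smoothed"` trace.
#' @return A data.frame with columns `stripe_id`, `ap_position`, `level`,
#'   `boundary`, `missing`.
#' @export
find_stripe_peaks <- function(trace, stripe_windows = default_stripe_windows(),
                              smooth_width = 3L,
                              level_from = c("raw", "smoothed")) {
  stopifnot(inherits(trace, "strip_trace"))
  level_from <- match.arg(level_from)
  sm <- .smooth_trace(trace$mean_intensity, smooth_width)
  lev <- if (level_from == "raw") trace$mean_intensity else sm
  lev[is.na(lev)] <- sm[is.na(lev)]  # empty raw bin: fall back to smoothed
  centers <- trace$ap_bin_centers
  out <- lapply(names(stripe_windows), function(id) {
    wn <- stripe_windows[[id]]
    in_w <- which(centers >= wn[1] & centers <= wn[2])
    v <- sm[in_w]
    if (length(in_w) == 0L || all(is.na(v))) {
      return(data.frame(stripe_id = id, ap_position = NA_real_,
                        level = NA_real_, boundary = NA,
                        missing = TRUE, stringsAsFactors = FALSE))
    }
    # interior local maxima: >= both neighbours, > at least one
    cand <- integer(0)
    for (k in seq_along(in_w)) {
      i <- in_w[k]
      if (i <= 1L || i >= length(sm)) next
      a <- sm[i - 1L]; b <- sm[i]; c <- sm[i + 1L]
      if (is.na(b) || is.na(a) || is.na(c)) next
      if (b >= a && b >= c && (b > a || b > c)) cand <- c(cand, i)
    }
    if (length(cand)) {
      best <- cand[which.max(sm[cand])]
      data.frame(stripe_id = id, ap_position = centers[best],
                 level = lev[best], boundary = FALSE, missing = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      best <- in_w[which.max(v)]
      data.frame(stripe_id = id, ap_position = centers[best],
                 level = lev[best], boundary = TRUE, missing = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Ventral minus lateral stripe peak difference
#'
#' The repression readout: lateral and ventral line traces are extracted,
#' jointly max-normalized (one embryo-wide maximum over both strips, so a
#' ventrally repressed peak stays below the lateral-defined maximum),
#' stripe peaks are found in each, and the per-stripe difference
#' `ventral - lateral` is returned. A decrease relative to control
#' embryos indicates ventral repression; an increase indicates
#' activation.
#'
#' @param pc A [pointcloud()].
#' @param channel Reporter channel, e.g. `"lacZ"`.
#' @param lateral,ventral [strip_spec()]s; defaults [lateral_strip()] and
#'   [ventral_strip()].
#' @param stripe_windows Named list of AP search windows.
#' @param smooth_width Peak-search smoothing width; default 3 bins.
#' @return A data.frame, one row per stripe: `embryo_id`, `genotype`,
#'   `timepoint`, `stripe_id`, `lateral_peak`, `ventral_peak`, `delta`
#'   (NA when either peak is missing), `boundary`.
#' @export
ventral_lateral_delta <- function(pc, channel,
                                  lateral = lateral_strip(),
                                  ventral = ventral_strip(),
                                  stripe_windows = default_stripe_windows(),
                                  smooth_width = 3L) {
  lt <- extract_strip_trace(pc, channel, lateral, "none")
  vt <- extract_strip_trace(pc, channel, ventral, "none")
  m <- max(c(lt$mean_intensity, vt$mean_intensity), na.rm = TRUE)
  if (!is.finite(m) || m <= 0)
    stop("embryo ", pc$embryo_id, ": channel '", channel,
         "' is all zero; cannot normalize")
  lt$mean_intensity <- lt$mean_intensity / m
  vt$mean_intensity <- vt$mean_intensity / m
  lt$normalization <- vt$normalization <- "max"
  lp <- find_stripe_peaks(lt, stripe_windows, smooth_width)
  vp <- find_stripe_peaks(vt, stripe_windows, smooth_width)
  data.frame(
    embryo_id = pc$embryo_id, genotype = pc$genotype,
    timepoint = pc$timepoint, stripe_id = lp$stripe_id,
    lateral_peak = lp$level, ventral_peak = vp$level,
    delta = vp$level - lp$level,
    boundary = lp$boundary | vp$boundary,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname ventral_lateral_delta
#' @param cohort A list of pointclouds.
#' @param ... Passed on to `ventral_lateral_delta`.
#' @export
cohort_deltas <- function(cohort, channel, ...) {
  do.call(rbind, lapply(cohort, ventral_lateral_delta, channel = channel,
                        ...))
}

#' Normalize stripe levels with an internal co-stain
#'
#' Absolute reporter levels cannot be compared across embryos because
#' staining efficiency varies; a co-stained reference gene expressed in
#' anterior/posterior caps (huckebein) provides a per-embryo scale. For
#' each embryo the co-stain peak over its cap domain is taken as the
#' scale factor and raw stripe peak levels are divided by it. Embryos
#' whose scale lies outside `median +/- 3 * MAD` of the cohort (or with a
#' zero co-stain peak) are discarded as staining outliers. The method is
#' only valid when reporter and co-stain levels co-vary across embryos,
#' so their Pearson correlation is computed and a warning is issued if it
#' is not significant at 0.05.
#'
#' @param cohort List of pointclouds from one staining batch, all with
#'   both channels.
#' @param signal_channel Reporter channel, e.g. `"lacZ"`.
#' @param costain_channel Reference channel, e.g. `"hkb"`.
#' @param strip Strip for the signal trace; default [lateral_strip()].
#' @param stripe_windows AP windows for signal peaks.
#' @param costain_domain AP domain of the co-stain caps as
#'   `c(anterior_max, posterior_min)`; default `c(0.1, 0.9)`.
#' @param mad_multiplier Outlier rule width; default 3.
#' @param smooth_width Peak-search smoothing; default 3 bins. The
#'   co-stain trace is smoothed with the same window before taking the
#'   cap maximum, so the scale factor is not dominated by single-bin
#'   sampling noise.
#' @return A list with `levels` (data.frame: embryo_id, genotype,
#'   timepoint, stripe_id, raw_level, scale, normalized_level),
#'   `embryos` (per-embryo scale and `dropped`/`reason`), and
#'   `correlation` (Pearson r and p between raw peak signal and co-stain
#'   scale across kept embryos).
#' @export
costain_normalize <- function(cohort, signal_channel, costain_channel,
                              strip = lateral_strip(),
                              stripe_windows = default_stripe_windows(),
                              costain_domain = c(0.1, 0.9),
                              mad_multiplier = 3, smooth_width = 3L) {
  stopifnot(length(cohort) >= 1L)
  per <- lapply(cohort, function(pc) {
    ct <- extract_strip_trace(pc, costain_channel, full_strip(), "none")
    smoothed <- .smooth_trace(ct$mean_intensity, smooth_width)
    cap <- ct$ap_bin_centers <= costain_domain[1] |
      ct$ap_bin_centers >= costain_domain[2]
    scale <- suppressWarnings(max(smoothed[cap], na.rm = TRUE))
    st <- extract_strip_trace(pc, signal_channel, strip, "none")
    pk <- find_stripe_peaks(st, stripe_windows, smooth_width)
    list(pc = pc, scale = scale, peaks = pk)
  })
  scales <- vapply(per, `[[`, numeric(1), "scale")
  reason <- rep(NA_character_, length(per))
  reason[!is.finite(scales) | scales <= 0] <- "zero_costain"
  ok <- is.na(reason)
  med <- median(scales[ok])
  dev <- mad(scales[ok])
  if (dev > 0) {
    out_of_band <- ok & abs(scales - med) > mad_multiplier * dev
    reason[out_of_band] <- "costain_outlier"
  }
  kept <- is.na(reason)
  embryos <- data.frame(
    embryo_id = vapply(per, function(p) p$pc$embryo_id, character(1)),
    genotype = vapply(per, function(p) p$pc$genotype, character(1)),
    scale = scales, dropped = !kept, reason = reason,
    stringsAsFactors = FALSE)
  levels <- do.call(rbind, lapply(which(kept), function(i) {
    p <- per[[i]]
    data.frame(embryo_id = p$pc$embryo_id, genotype = p$pc$genotype,
               timepoint = p$pc$timepoint, stripe_id = p$peaks$stripe_id,
               raw_level = p$peaks$level, scale = p$scale,
               normalized_level = p$peaks$level / p$scale,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  correlation <- list(r = NA_real_, pvalue = NA_real_)
  if (sum(kept) >= 3L) {
    raw_peak <- vapply(which(kept), function(i)
      max(per[[i]]$peaks$level, na.rm = TRUE), numeric(1))
    ct <- cor.test(raw_peak, scales[kept], method = "pearson")
    correlation <- list(r = unname(ct$estimate), pvalue = ct$p.value)
    if (is.na(ct$p.value) || ct$p.value >= 0.05)
      warning("reporter and co-stain levels are not significantly ",
              "correlated across embryos (p = ",
              signif(ct$p.value, 3), "); co-stain normalization may be ",
              "unreliable for this batch")
  }
  list(levels = levels, embryos = embryos, correlation = correlation)
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two samples, the test used throughout for
#' genotype and construct comparisons. The p-value is exact (full
#' enumeration of rank assignments) when `n_a * n_b <= 400` and there are
#' no ties, and otherwise uses the normal approximation with tie and
#' continuity corrections.
#'
#' @param sample_a,sample_b Numeric vectors, each with at least one value.
#' @return A list with `U` (for `sample_a`), `pvalue`, `exact` (logical)
#'   and the sample sizes.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mann_whitney_u <- function(sample_a, sample_b) {
  sample_a <- as.numeric(sample_a)
  sample_b <- as.numeric(sample_b)
  if (length(sample_a) < 1L || length(sample_b) < 1L)
    stop("both samples need at least one value")
  if (anyNA(sample_a) || anyNA(sample_b))
    stop("missing values are not allowed")
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0L
  exact <- !ties && length(sample_a) * length(sample_b) <= 400
  wt <- suppressWarnings(
    wilcox.test(sample_a, sample_b, alternative = "two.sided",
                exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), pvalue = wt$p.value, exact = exact,
       n_a = length(sample_a), n_b = length(sample_b))
}
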