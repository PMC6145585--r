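#' Simulate background sequence with planted binding sites
#'
#' Draws i.i.d. background bases at the requested GC content and plants
#' binding-site instances at uniformly chosen, non-overlapping positions.
#' Site letters come either from each matrix's consensus or are sampled
#' from its pseudocount-smoothed frequencies; reverse-strand instances
#' are planted as the reverse complement. A truth table of every planted
#' site is returned for downstream validation.
#'
#' @param n_records Number of sequence records; default 1.
#' @param length Length of each record.
#' @param gc_content GC fraction in (0, 1); default 0.5.
#' @param planted_sites List of plantings, each a list with elements
#'   `wm` (a [build_weight_matrix()] result) and either `count` (sites
#'   per record) or `rate` (expected sites per base pair, Poisson);
#'   optional `strands` (`"both"` default, or `"forward"`) and `mode`
#'   (`"consensus"` default, or `"frequency"`).
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `records` (named character vector of sequences)
#'   and `truth` (data.frame: record_id, tf_name, start (0-based),
#'   strand, site).
#' @export
simulate_sequences <- function(n_records = 1L, length, gc_content = 0.5,
                               planted_sites = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- as.numeric(gc_background(gc_content))
  records <- character(n_records)
  names(records) <- paste0("seq_", seq_len(n_records))
  truth <- list()
  for (r in seq_len(n_records)) {
    chars <- sample(DNA_BASES, length, replace = TRUE, prob = p)
    occupied <- integer(0)  # 1-based positions covered by planted sites
    for (ps in planted_sites) {
      wm <- ps$wm
      w <- motif_width(wm)
      count <- if (!is.null(ps$count)) ps$count else rpois(1, ps$rate * length)
      strands <- if (is.null(ps$strands)) "both" else ps$strands
      mode <- if (is.null(ps$mode)) "consensus" else ps$mode
      freqs <- .implied_frequencies(wm)
      placed <- 0L
      tries <- 0L
      while (placed < count) {
        tries <- tries + 1L
        if (tries > 1000L * max(count, 1L))
          stop("could not place ", count, " non-overlapping sites of '",
               wm$tf_name, "' in a sequence of length ", length)
        start <- sample.int(length - w + 1L, 1L)
        span <- start:(start + w - 1L)
        if (any(span %in% occupied)) next
        strand <- if (strands == "both") sample(c("+", "-"), 1L) else "+"
        site <- if (mode == "consensus") {
          consensus_sequence(wm)
        } else {
          paste(vapply(seq_len(w), function(j)
            sample(DNA_BASES, 1L, prob = freqs[j, ]), character(1)),
            collapse = "")
        }
        planted <- if (strand == "-") .revcomp(site) else site
        chars[span] <- strsplit(planted, "", fixed = TRUE)[[1L]]
        occupied <- c(occupied, span)
        truth[[base::length(truth) + 1L]] <- data.frame(
          record_id = names(records)[r], tf_name = wm$tf_name,
          start = start - 1L, strand = strand, site = site,
          stringsAsFactors = FALSE)
        placed <- placed + 1L
      }
    }
    records[r] <- paste(chars, collapse = "")
  }
  list(records = records,
       truth = if (length(truth)) do.call(rbind, truth) else data.frame(
         record_id = character(0), tf_name = character(0),
         start = integer(0), strand = character(0), site = character(0),
         stringsAsFactors = FALSE))
}

#' Simulate an enhancer ortholog family with correlated site counts
#'
#' Emulates an orthologous enhancer set across species in which the site
#' counts of two factors co-vary. Per-species counts for the two factors
#' are drawn from Poisson marginals coupled by a Gaussian copula whose
#' latent correlation is chosen to target the requested Spearman
#' correlation (`r_latent = 2 sin(pi rho / 6)`); consensus sites are then
#' planted non-overlapping in i.i.d. background sequence. Poisson
#' discretisation ties attenuate the realized rank correlation slightly;
#' the realized value on the true counts is returned alongside.
#'
#' @param n_species Number of orthologs (>= 4).
#' @param seq_length Length of each ortholog sequence.
#' @param wm_a,wm_b Weight matrices for the two factors.
#' @param lambda_a,lambda_b Poisson means of the per-species site counts.
#' @param target_rho Target Spearman correlation of the counts, in
#'   \[-1, 1\].
#' @param gc_content Background GC fraction; default 0.5.
#' @param seed Optional integer seed.
#' @return A list with `records` (named character vector, one per
#'   species), `truth` (data.frame: species, count_a, count_b) and
#'   `realized_rho` (Spearman correlation of the true planted counts).
#' @export
simulate_ortholog_family <- function(n_species, seq_length, wm_a, wm_b,
                                     lambda_a = 3, lambda_b = 3,
                                     target_rho = 0, gc_content = 0.5,
                                     seed = NULL) {
  if (n_species < 4L) stop("need at least 4 species")
  if (abs(target_rho) > 1) stop("target_rho must be in [-1, 1]")
  if (!is.null(seed)) set.seed(seed)
  r_lat <- 2 * sin(pi * target_rho / 6)
  r_lat <- max(-1, min(1, r_lat))
  z1 <- rnorm(n_species)
  z2 <- r_lat * z1 + sqrt(1 - r_lat^2) * rnorm(n_species)
  counts_a <- qpois(pnorm(z1), lambda_a)
  counts_b <- qpois(pnorm(z2), lambda_b)
  feasible <- counts_a * motif_width(wm_a) + counts_b * motif_width(wm_b)
  if (any(feasible > 0.5 * seq_length))
    stop("planted site counts do not fit in sequences of length ",
         seq_length)
  species <- sprintf("species_%02d", seq_len(n_species))
  records <- character(n_species)
  names(records) <- species
  for (i in seq_len(n_species)) {
    sim <- simulate_sequences(
      n_records = 1L, length = seq_length, gc_content = gc_content,
      planted_sites = list(list(wm = wm_a, count = counts_a[i]),
                           list(wm = wm_b, count = counts_b[i])))
    records[i] <- sim$records[[1L]]
  }
  realized <- if (sd(counts_a) == 0 || sd(counts_b) == 0) NA_real_ else
    cor(rank(counts_a), rank(counts_b))
  list(records = records,
       truth = data.frame(species = species, count_a = counts_a,
                          count_b = counts_b, stringsAsFactors = FALSE),
       realized_rho = realized)
}

#' Specification of a synthetic blastoderm embryo
#'
#' Parameters of the generative model behind [simulate_embryo_cohort()]:
#' nuclei uniform on the AP x DV surface; a reporter channel that is a
#' sum of Gaussian AP stripes, each attenuated ventrally by
#' `(1 - rho * V(dv))` where `V` is a flat-topped cosine window centred
#' on the ventral midline (V = 1 on a plateau of half-width
#' `ventral_plateau`, cosine taper over a further `ventral_taper`); a
#' co-stain channel confined to anterior/posterior caps; additive
#' Gaussian measurement noise truncated at zero; and a per-embryo
#' lognormal gain applied to all channels after noise, emulating
#' embryo-to-embryo staining efficiency.
#'
#' @param n_nuclei Nuclei per embryo; default 6000 (blastoderm scale).
#' @param stripes data.frame with columns `id`, `ap_center`, `ap_sd`,
#'   `amplitude`.
#' @param ventral_effect Named numeric vector of per-stripe ventral
#'   factors rho in \[-1, 1\] (positive = repression); stripes not named
#'   get 0.
#' @param ventral_plateau,ventral_taper Half-widths (circumference
#'   fraction) of the ventral window's plateau and cosine taper;
#'   defaults 0.05 and 0.05 (total half-width 0.1).
#' @param costain_amplitude Cap amplitude of the co-stain channel.
#' @param noise_sd Additive Gaussian noise SD (intensity units, before
#'   the embryo gain); default 0.05.
#' @param intensity_lnorm_sd SD of the per-embryo lognormal gain (log
#'   scale); default 0.4.
#' @param genotype Genotype label stamped on each embryo.
#' @param timepoints Timepoints to assign (cycled); default 1:6.
#' @return An object of class `embryo_sim_spec`.
#' @export
embryo_sim_spec <- function(n_nuclei = 6000L,
                            stripes = data.frame(
                              id = c(2, 3, 7),
                              ap_center = c(0.40, 0.50, 0.85),
                              ap_sd = 0.02, amplitude = 1),
                            ventral_effect = c(),
                            ventral_plateau = 0.05, ventral_taper = 0.05,
                            costain_amplitude = 1,
                            noise_sd = 0.05,
                            intensity_lnorm_sd = 0.4,
                            genotype = "wild_type",
                            timepoints = 1:6) {
  if (any(stripes$amplitude < 0)) stop("stripe amplitudes must be >= 0")
  if (any(stripes$ap_sd <= 0)) stop("stripe ap_sd must be positive")
  rho <- setNames(rep(0, nrow(stripes)), as.character(stripes$id))
  if (length(ventral_effect)) {
    unknown <- setdiff(names(ventral_effect), names(rho))
    if (length(unknown))
      stop("ventral_effect names unknown stripes: ",
           paste(unknown, collapse = ", "))
    if (any(abs(ventral_effect) > 1))
      stop("ventral_effect values must be in [-1, 1]")
    rho[names(ventral_effect)] <- ventral_effect
  }
  structure(list(n_nuclei = as.integer(n_nuclei), stripes = stripes,
                 ventral_effect = rho, ventral_plateau = ventral_plateau,
                 ventral_taper = ventral_taper,
                 costain_amplitude = costain_amplitude,
                 noise_sd = noise_sd,
                 intensity_lnorm_sd = intensity_lnorm_sd,
                 genotype = genotype, timepoints = timepoints),
            class = "embryo_sim_spec")
}

# Flat-topped cosine ventral window: 1 on |dv - 0.5| <= plateau, cosine
# decay to 0 over the next `taper`, 0 beyond.
.ventral_window <- function(dv, plateau, taper) {
  d <- abs(dv - 0.5)
  out <- numeric(length(dv))
  out[d <= plateau] <- 1
  tz <- d > plateau & d < plateau + taper
  out[tz] <- 0.5 * (1 + cos(pi * (d[tz] - plateau) / taper))
  out
}

#' Simulate a cohort of synthetic embryos
#'
#' Generates `n_embryos` pointclouds from an [embryo_sim_spec()] together
#' with a truth table of the planted parameters. Nuclei are uniform on
#' the AP x DV surface; the reporter channel `lacZ` is
#' `sum_s amplitude_s * exp(-(ap - c_s)^2 / (2 sd_s^2)) * (1 - rho_s V(dv))`,
#' the co-stain channel `hkb` occupies anterior/posterior caps (soft
#' logistic edges at AP 0.08 and 0.92), both are perturbed by truncated
#' Gaussian noise and then multiplied by the embryo's lognormal gain.
#'
#' @param spec An [embryo_sim_spec()].
#' @param n_embryos Number of embryos (>= 1).
#' @param seed Optional integer seed.
#' @param id_prefix Prefix for embryo ids; default the genotype label.
#' @return A list with `cohort` (list of [pointcloud()]s) and `truth`
#'   (data.frame: embryo_id, genotype, timepoint, gain, and the
#'   per-stripe planted rho as `rho_<id>` columns).
#' @export
simulate_embryo_cohort <- function(spec, n_embryos, seed = NULL,
                                   id_prefix = NULL) {
  stopifnot(inherits(spec, "embryo_sim_spec"), n_embryos >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(id_prefix)) id_prefix <- spec$genotype
  cohort <- vector("list", n_embryos)
  truth <- vector("list", n_embryos)
  for (e in seq_len(n_embryos)) {
    gain <- rlnorm(1, 0, spec$intensity_lnorm_sd)
    ap <- runif(spec$n_nuclei)
    dv <- runif(spec$n_nuclei)
    V <- .ventral_window(dv, spec$ventral_plateau, spec$ventral_taper)
    signal <- numeric(spec$n_nuclei)
    for (s in seq_len(nrow(spec$stripes))) {
      st <- spec$stripes[s, ]
      rho <- spec$ventral_effect[[as.character(st$id)]]
      signal <- signal + st$amplitude *
        exp(-(ap - st$ap_center)^2 / (2 * st$ap_sd^2)) * (1 - rho * V)
    }
    costain <- spec$costain_amplitude *
      (plogis((0.08 - ap) / 0.01) + plogis((ap - 0.92) / 0.01))
    lacZ <- gain * pmax(0, signal + rnorm(spec$n_nuclei, 0, spec$noise_sd))
    hkb <- gain * pmax(0, costain + rnorm(spec$n_nuclei, 0, spec$noise_sd))
    timepoint <- spec$timepoints[((e - 1L) %% length(spec$timepoints)) + 1L]
    embryo_id <- sprintf("%s_%03d", id_prefix, e)
    cohort[[e]] <- pointcloud(
      embryo_id, spec$genotype, timepoint,
      data.frame(ap = ap, dv = dv, lacZ = lacZ, hkb = hkb))
    truth[[e]] <- data.frame(
      embryo_id = embryo_id, genotype = spec$genotype,
      timepoint = timepoint, gain = gain, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  for (id in names(spec$ventral_effect)) {
    truth[[paste0("rho_", id)]] <- spec$ventral_effect[[id]]
  }
  list(cohort = cohort, truth = truth)
}
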