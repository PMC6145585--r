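---
title: "Models and methods behind stripescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stripescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stripescan)
```

This vignette is the package's own account of its models, the choices
made where the underlying experimental design left details open, and
what the synthetic-data tests do and do not establish about real data.

## 1. Weight matrices and scanning

A factor's binding preference enters as a count matrix (width × 4,
A,C,G,T). With pseudocount $s$ (default 1) apportioned in proportion to
the background frequencies $p_b$ — the PATSER convention — the smoothed
frequency and natural-log-odds weight at position $i$ are

$$f_{ib} = \frac{c_{ib} + s\,p_b}{N_i + s}, \qquad
  w_{ib} = \ln(f_{ib}/p_b).$$

Design notes:

* **Log base.** Natural log. Score *rankings*, thresholds derived from
  the same distribution, and enrichment ratios are all base-agnostic,
  so nothing downstream depends on this choice.
* **Background.** Uniform by default and configurable
  (`background_model()`, `gc_background()`); published analyses rarely
  state the background actually used, so it is an explicit parameter
  rather than a constant.
* **Coordinates.** 0-based, half-open, like BED. Reverse-strand hits are
  reported in forward coordinates; the reverse-strand score of a window
  is the forward score of its reverse complement.
* **N handling.** Windows containing `N` are skipped (they score `NA`
  internally and are never compared against the threshold).

## 2. Exact score p-values

The null distribution of a single window score under i.i.d. background
bases is computed exactly by dynamic programming: weights are rounded to
an integer lattice of spacing `granularity` (default $10^{-3}$ score
units) and the per-position distributions are convolved. The probability
mass on the lattice is exact; the only approximation is the lattice
itself, which displaces any achievable score by at most
$\tfrac{1}{2} w \cdot g$ for width $w$.

`threshold_for_pvalue(dist, p)` picks the smallest *achievable* lattice
score whose tail probability is ≤ `p`, then subtracts the
$\tfrac{1}{2} w g$ rounding slack so that every window whose rounded
score satisfies the tail bound also passes on its exact score. The
subtraction can admit a sliver of extra windows whose rounded score sits
one lattice step below the cutoff; with the default granularity this
changes the realized false-positive rate by far less than the binomial
noise of any finite scan (the acceptance suite verifies the rate bound
empirically over $10^6$ windows). Degenerate cases: a requested p-value
of 1 returns the minimum score; a p-value below the smallest attainable
tail returns a value above the maximum score with a warning; a
granularity so coarse that genuinely different weights collapse to one
lattice point is rejected.

## 3. Knockout mutation design

`design_knockout_mutations()` removes every site of a target factor
above the p-value cutoff (default 0.003) while treating the site lists
of other factors as frozen. Per target site, candidate single-base edits
are evaluated at window positions in decreasing order of the target
matrix's information content; an edit is admissible only if it neither
creates nor destroys any protected-factor hit (at that factor's own
cutoff) within the neighbourhood that the edit can influence. Among
admissible edits the one minimizing the rescored target window wins;
ties prefer transversions (they usually move scores furthest), then the
smaller position, then alphabetical order of the new base — a fully
deterministic rule. Sites with no admissible path below threshold are
left unmutated and flagged `protected_conflict`; a site that survives
the per-site edit budget (default 3) is flagged `max_edits_reached`.
This operationalizes the practice of leaving some low-affinity sites
untouched rather than damaging overlapping sites of other regulators:
the published record does not state whether such sites were chosen by a
score rule or by inspection, so the package makes the rule explicit and
reports every flagged site. The whole-sequence before/after scan of all
factors (`collateral_report`) is returned so no side effect is silent.

Protected-hit identity is (position, strand): an edit that merely lowers
a surviving protected site's score is allowed, matching a
create-or-destroy reading of "predicted effects on all predicted sites".

## 4. Enrichment and co-evolution

The null expectation for an enhancer of length $L$ is the per-window hit
rate $r_t$ measured on background sequence (in practice, accessible
regions of the stage-5 genome; here any FASTA set), scaled to the
enhancer's $2(L - w + 1)$ scannable (position, strand) pairs. The score
is $\log_2 \frac{\text{obs} + 0.5}{\text{exp} + 0.5}$:

* The 0.5 smoothing keeps the score finite at zero counts and preserves
  the sign convention (positive iff the observed density exceeds the
  background density). The exact smoothing constant only matters when
  expected counts are small; the acceptance calibration therefore
  evaluates enhancers long enough for expected counts ≈ 40, where the
  concave bias of the log-ratio is negligible.
* Overlapping hits each count once per (position, strand) — sites are
  counted, not merged.
* Because the defensible score threshold is genuinely uncertain,
  `threshold_sensitivity_scan()` recomputes everything at every integer
  threshold from 1 to the larger matrix maximum. Thresholds where an
  enrichment vector has fewer than three distinct values yield an
  undefined correlation recorded with a reason code — never silently
  dropped, and never coerced to 0.

Spearman's rho is the Pearson correlation of mid-ranks. For n ≤ 9 the
two-sided p-value is exact by enumerating all n! permutations; beyond
that a t-approximation with n − 2 degrees of freedom is used. No
phylogenetic correction is applied across ortholog species — the
correlations are descriptive, as in the source analysis tradition, and
species non-independence is a documented caveat.

## 5. Stripe expression statistics

Pointclouds are per-nucleus tables: AP position as a fraction (0 =
anterior), DV position as a circumference fraction (0 = dorsal midline,
0.5 = ventral midline), and one intensity column per channel.

* **Strips.** The lateral strip defaults to both lateral bands
  [0.20, 0.30) ∪ [0.70, 0.80), the ventral strip to [0.45, 0.55). Strip
  extents are not published for the original measurements; these widths
  are comfortably inside the ventral-misexpression domain and average
  the two symmetric lateral bands. All are configurable.
* **Traces.** 100 equal AP bins, per-bin arithmetic means; empty bins
  are missing. AP stripe search windows default to stripe 2 [0.33,
  0.47], stripe 3 [0.42, 0.55], stripe 7 [0.78, 0.92] — these bracket
  the synthetic generator's stripe positions and must be set per
  enhancer for real data.
* **Peaks.** The trace is smoothed with a 3-bin moving average to steady
  the peak location, but the reported level is read from the unsmoothed
  trace at that bin: whether peak heights came from smoothed or raw
  traces is unstated in the source, and the raw-level choice keeps a
  planted ventral attenuation identifiable instead of multiplying it by
  the smoothing kernel's attenuation. Windows without an interior local
  maximum return the window maximum with a `boundary` flag.
* **Delta.** Both strips are normalized by a single embryo-wide maximum
  over the two traces before subtracting, so a repressed ventral peak
  can fall below a lateral-defined maximum; per-strip normalization
  would clamp both peaks to 1 and erase the effect. The delta is
  invariant to any positive rescaling of the embryo's intensities.
* **Co-stain levels.** The scale factor is the smoothed co-stain trace
  maximum over the cap domain (AP ≤ 0.1 or ≥ 0.9); smoothing matters
  here because a raw binned maximum over ~20 bins converts bin-sampling
  noise into a systematic, embryo-specific scale error. Embryos with a
  zero co-stain peak or a scale outside median ± 3·MAD are dropped with
  a reason; the cohort-level Pearson correlation between reporter and
  co-stain peaks is reported and a warning raised when it is not
  significant at 0.05, since the normalization is meaningless for
  batches where staining efficiency does not co-vary across channels.
* **Mann-Whitney U.** Exact by enumeration when $n_a n_b \le 400$ with
  no ties; otherwise normal approximation with tie and continuity
  corrections (delegated to R's `wilcox.test`, with the switch made
  explicit). Ties are mid-ranked.
* **Timepoints.** Filtering is the caller's responsibility: deltas are
  typically pooled over all six stage-5 timepoints while co-stain level
  comparisons use mid timepoints, so no filter is hard-wired.

## 6. The synthetic-data generator

The generator encodes the statistical structure the analyses assume, not
enhancer biophysics:

* **Sequences.** i.i.d. bases at a chosen GC content; sites planted
  non-overlapping at uniform positions, as the matrix consensus
  (default) or draws from its implied frequencies; every planting is
  recorded in a truth table.
* **Ortholog families.** Per-species site counts for two factors are
  Poisson marginals coupled by a Gaussian copula; the latent correlation
  is set to $2\sin(\pi\rho/6)$ to target a Spearman correlation $\rho$.
  Poisson ties attenuate the realized rank correlation by a few
  hundredths at the default mean of 3 — the realized value on the true
  counts is returned with each family, and recovery tests compare
  against the *target* with tolerances that absorb the attenuation.
* **Embryos.** Nuclei uniform on the AP × DV rectangle (real nuclei are
  packed quasi-hexagonally, but binned means at thousands of nuclei are
  insensitive to packing). The reporter is a sum of Gaussian AP stripes
  (defaults: stripes 2, 3, 7 at AP 0.40, 0.50, 0.85, sd 0.02, equal
  amplitudes) attenuated ventrally by $1 - \rho V(dv)$. $V$ is a
  flat-topped cosine window centred on the ventral midline: plateau
  half-width 0.05 — covering the default ventral strip so the planted
  $\rho$ maps one-to-one onto the expected delta — with a cosine taper
  over a further 0.05 (total half-width 0.1). A pure cosine bump of the
  same half-width would attenuate the ventral-strip mean to ≈ 0.82ρ and
  make the planted effect unrecoverable at the stated tolerances, which
  is why the plateau exists. The co-stain occupies anterior/posterior
  caps with soft logistic edges at AP 0.08/0.92. Gaussian measurement
  noise (sd 0.05) is truncated at zero and added *before* the
  per-embryo lognormal gain (default log-sd 0.4), so the gain multiplies
  all channels coherently — this is what makes co-stain normalization
  exactly identifiable, and it mirrors staining efficiency acting on
  the whole embryo. Default 6000 nuclei per embryo, the scale of the
  cellularizing blastoderm.

Sampling jitter means a noise-free embryo's delta is only zero to within
the binning resolution (~0.02 with the defaults); tests on random
cohorts use tolerances, and the exact-zero expectation is checked on a
deterministic nucleus grid instead.

## 7. Problem sizes and what the tests show

The test suite's end-to-end checks run, per run: 100 random
matrix/sequence scan-oracle pairs; exhaustive 4^w enumerations for
widths 2–8; a $10^6$-window false-positive scan; enrichment calibration
on 50 kb enhancers (expected chance counts ≈ 40); 200 + 200 simulated
23-species ortholog families; 40-embryo genotype cohorts plus 50
replicate stripe-2 null cohorts; 200 null cohorts for the type-I rate;
and 40 + 40-embryo co-stain cohorts (a variance *ratio* needs this many
degrees of freedom to be a stable statistic). These sizes were chosen so
each Monte-Carlo check has tolerance headroom of at least ~3 standard
errors.

Passing them shows the implementation is internally correct and
calibrated under the generator's assumptions — Gaussian stripes, uniform
nuclei, coherent multiplicative gain, i.i.d. background sequence. Real
embryos and genomes violate all of these in degree (patterned nucleus
density, spatially structured staining artifacts, repeat-laden
background with covarying GC), so the tests validate the *machinery*,
not any biological conclusion drawn from a particular dataset.

## 8. Known limitations

* Background sequence is taken as given; the package does not call
  accessible regions or fetch genomes, and enrichment inherits any bias
  in the supplied background set.
* No phylogenetic correction in the co-evolution analysis (above).
* Strip geometry assumes the standard registration conventions; badly
  registered pointclouds should be repaired upstream.
* The mutation designer is greedy per site; it will not find multi-site
  joint solutions that a global optimizer might, which matches how such
  constructs are designed in practice but is not guaranteed optimal.
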