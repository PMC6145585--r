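aa_wm <- consensus_wm("AA", "AA", strength = 9)

test_that("background rate counts hits per (position, strand) pair", {
  # AAAA under a width-2 AA-maximal matrix at max score: 3 forward hits,
  # none on the reverse strand, 6 scannable pairs
  rate <- estimate_background_rate(aa_wm, aa_wm$max_score,
                                   c(bg = "AAAA"))
  expect_equal(rate$hits_per_position, 3 / 6)
  expect_equal(rate$positions_scanned, 6L)
  # a hit-free background
  rate0 <- estimate_background_rate(aa_wm, aa_wm$max_score,
                                    c(bg = "CGCGCGCG"))
  expect_equal(rate0$hits_per_position, 0)
  expect_error(estimate_background_rate(aa_wm, 0, character(0)), "empty")
})

test_that("splitting a background record only loses boundary windows", {
  set.seed(41)
  wm <- build_weight_matrix(rand_count_matrix(4))
  seq <- rand_dna(2000)
  thr <- wm$min_score + 0.7 * (wm$max_score - wm$min_score)
  whole <- estimate_background_rate(wm, thr, c(a = seq))
  halves <- estimate_background_rate(
    wm, thr, c(a = substr(seq, 1, 1000), b = substr(seq, 1001, 2000)))
  # 3 boundary windows per strand are lost; counts differ at most by that
  expect_lte(abs(whole$hits - halves$hits), 6)
  expect_equal(whole$positions_scanned - halves$positions_scanned, 6)
})

test_that("enrichment score is the smoothed log2 observed/expected", {
  # AAAAA gives 4 forward AA hits in 8 pairs; a rate of 1/8 makes the
  # expectation exactly 1, so the unsmoothed score is log2(4) = 2
  rate <- estimate_background_rate(aa_wm, aa_wm$max_score,
                                   c(bg = "AATT"))  # 1 + 1 hits / 6+...
  rate$hits_per_position <- 1 / 8
  res <- compute_enrichment("AAAAA", aa_wm, aa_wm$max_score, rate,
                            smoothing = 0)
  expect_equal(res$observed_count, 4L)
  expect_equal(res$expected_count, 1)
  expect_equal(res$score, 2)
  # observed equal to expected: score 0 by construction
  rate$hits_per_position <- 4 / 8
  res <- compute_enrichment("AAAAA", aa_wm, aa_wm$max_score, rate,
                            smoothing = 0.5)
  expect_equal(res$score, 0)
})

test_that("mismatched rate metadata is rejected", {
  rate <- estimate_background_rate(aa_wm, aa_wm$max_score, c(bg = "AAAA"))
  expect_error(compute_enrichment("AAAA", aa_wm, 0, rate), "threshold")
  other <- consensus_wm("other", "CC")
  expect_error(
    compute_enrichment("AAAA", other, aa_wm$max_score, rate), "rate")
})

test_that("planting above the background rate gives positive scores, masking negative", {
  set.seed(42)
  wm <- consensus_wm("site", "ACGTAC")
  bg <- simulate_sequences(1, 50000, seed = 420)$records
  thr <- floor(wm$max_score)
  rate <- estimate_background_rate(wm, thr, bg)
  planted <- simulate_sequences(1, 2000, seed = 421,
                                planted_sites = list(list(wm = wm, count = 8)))
  res <- compute_enrichment(planted$records[[1]], wm, thr, rate)
  expect_gt(res$score, 0)
  # masking: sequence with no sites at all (G/C only cannot hold ACGTAC)
  masked <- paste(sample(c("C", "G"), 2000, TRUE), collapse = "")
  res0 <- compute_enrichment(masked, wm, thr, rate)
  expect_lt(res0$score, 0)
})

test_that("spearman correlation matches closed forms and the permutation oracle", {
  expect_equal(spearman_correlation(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_correlation(1:3, c(3, 2, 1))$rho, -1)
  set.seed(43)
  for (i in 1:10) {
    x <- rnorm(4)
    y <- rnorm(4)
    got <- spearman_correlation(x, y)
    want <- oracle_spearman_exact(x, y)
    expect_equal(got$rho, want$rho)
    expect_equal(got$pvalue, want$pvalue)  # 24-permutation enumeration
  }
  # with ties, mid-ranks
  expect_equal(spearman_correlation(c(1, 1, 2, 3), c(4, 4, 5, 6))$rho,
               cor(c(1, 1, 2, 3), c(4, 4, 5, 6), method = "spearman"))
  # constant input is signalled, not silently zeroed
  res <- spearman_correlation(rep(1, 5), 1:5)
  expect_true(is.na(res$rho))
  expect_equal(res$reason, "constant_input")
})

test_that("the t-approximation tracks cor.test for larger samples", {
  set.seed(44)
  x <- rnorm(23)
  y <- x + rnorm(23, sd = 2)
  got <- spearman_correlation(x, y)
  want <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(got$rho, unname(want$estimate))
  expect_equal(got$pvalue, want$p.value, tolerance = 1e-10)
})

test_that("rho is invariant to strictly monotone transforms", {
  set.seed(45)
  x <- rnorm(12)
  y <- rnorm(12)
  base <- spearman_correlation(x, y)$rho
  expect_equal(spearman_correlation(exp(x), y)$rho, base)
  expect_equal(spearman_correlation(x, y^3 + 5 * y)$rho, base)
})

test_that("sensitivity scan recovers planted perfect co-variation", {
  set.seed(46)
  # width 8: a chance consensus in 800 bp is ~1e-2 per species, and a
  # single chance hit cannot reorder counts spaced 2 apart
  wm_a <- consensus_wm("A8", "ACGTACGT")
  wm_b <- consensus_wm("B8", "GTTAGTCA")
  counts <- c(1, 3, 5, 7, 9, 11)
  records <- vapply(counts, function(k) {
    simulate_sequences(1, 800, planted_sites = list(
      list(wm = wm_a, count = k), list(wm = wm_b, count = k)))$records[[1]]
  }, character(1))
  names(records) <- paste0("sp", seq_along(records))
  bg <- simulate_sequences(1, 40000)$records
  res <- threshold_sensitivity_scan(records, wm_a, wm_b, bg)
  t_plant <- floor(min(wm_a$max_score, wm_b$max_score))
  i <- match(t_plant, res$thresholds)
  expect_equal(res$rho[i], 1)
  # enrichment table covers both factors at every threshold
  expect_setequal(unique(res$enrichment$tf_name), c("A8", "B8"))
  expect_error(threshold_sensitivity_scan(records[1:3], wm_a, wm_b, bg),
               "at least 4")
})

test_that("thresholds beyond the score range are flagged, not dropped", {
  wm_a <- consensus_wm("A4", "ACGT", strength = 50)
  wm_b <- consensus_wm("B4", "GGTA", strength = 50)
  records <- setNames(
    c("CCCCCCCCCCCC", "CCCCCCCCCCCC", "CCCCCCCCCCCC", "CCCCCCCCCCCC"),
    paste0("sp", 1:4))
  res <- threshold_sensitivity_scan(records, wm_a, wm_b,
                                    c(bg = "CCCCCCCCCCCCCCCC"))
  # hit-free orthologs: enrichment is constant everywhere -> rho undefined
  expect_true(all(is.na(res$rho)))
  expect_true(all(res$reason == "constant_enrichment"))
  expect_equal(length(res$thresholds),
               floor(max(wm_a$max_score, wm_b$max_score)))
})
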