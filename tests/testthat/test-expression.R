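# A deterministic toy embryo: nuclei on a regular grid, one Gaussian
# stripe at a known AP position with optional ventral attenuation.
grid_embryo <- function(ap_centers = c(0.45), amps = 1, vfactor = 0,
                        n_ap = 200, n_dv = 40, id = "toy",
                        genotype = "wild_type") {
  ap <- rep((seq_len(n_ap) - 0.5) / n_ap, each = n_dv)
  dv <- rep((seq_len(n_dv) - 0.5) / n_dv, times = n_ap)
  sig <- numeric(length(ap))
  for (i in seq_along(ap_centers)) {
    sig <- sig + amps[min(i, length(amps))] *
      exp(-(ap - ap_centers[i])^2 / (2 * 0.02^2))
  }
  ventral <- abs(dv - 0.5) <= 0.05
  sig[ventral] <- sig[ventral] * (1 - vfactor)
  pointcloud(id, genotype, 3, data.frame(ap = ap, dv = dv, lacZ = sig,
                                         hkb = 1 + 0 * ap))
}

test_that("strip traces are per-bin means with optional max-normalization", {
  pc <- pointcloud("const", "wild_type", 1,
                   data.frame(ap = runif(500), dv = runif(500),
                              lacZ = 5, hkb = 1))
  tr <- extract_strip_trace(pc, "lacZ", lateral_strip(), "none")
  expect_true(all(tr$mean_intensity[!is.na(tr$mean_intensity)] == 5))
  trm <- extract_strip_trace(pc, "lacZ", lateral_strip(), "max")
  expect_true(all(trm$mean_intensity[!is.na(trm$mean_intensity)] == 1))
  # all-zero channel cannot be max-normalized
  pc0 <- pointcloud("zero", "wild_type", 1,
                    data.frame(ap = runif(50), dv = runif(50), lacZ = 0))
  expect_error(extract_strip_trace(pc0, "lacZ", lateral_strip(), "max"),
               "all zero")
  expect_error(extract_strip_trace(pc, "nope", lateral_strip()),
               "no channel")
})

test_that("a planted Gaussian stripe peaks at its planted AP position", {
  pc <- grid_embryo(ap_centers = 0.45)
  tr <- extract_strip_trace(pc, "lacZ", lateral_strip(), "max")
  argmax <- tr$ap_bin_centers[which.max(tr$mean_intensity)]
  expect_lt(abs(argmax - 0.45), 0.02)
})

test_that("nuclei outside the strip windows do not influence the trace", {
  set.seed(51)
  n <- 4000
  nuc <- data.frame(ap = runif(n), dv = runif(n), lacZ = runif(n))
  pc_all <- pointcloud("a", "wild_type", 2, nuc)
  inside <- stripescan:::.in_strip(nuc$dv, lateral_strip())
  pc_in <- pointcloud("a", "wild_type", 2, nuc[inside, ])
  t1 <- extract_strip_trace(pc_all, "lacZ", lateral_strip())
  t2 <- extract_strip_trace(pc_in, "lacZ", lateral_strip())
  expect_equal(t1$mean_intensity, t2$mean_intensity)
})

test_that("stripe peaks are found at planted centers and stay local", {
  pc <- grid_embryo(ap_centers = c(0.45, 0.85))
  tr <- extract_strip_trace(pc, "lacZ", lateral_strip(), "max")
  pk <- find_stripe_peaks(tr, list(s1 = c(0.35, 0.55), s2 = c(0.75, 0.95)))
  expect_equal(pk$stripe_id, c("s1", "s2"))
  expect_lt(abs(pk$ap_position[1] - 0.45), 0.015)
  expect_lt(abs(pk$ap_position[2] - 0.85), 0.015)
  expect_false(any(pk$boundary))
  # a third stripe outside every window changes nothing
  pc3 <- grid_embryo(ap_centers = c(0.45, 0.85, 0.65))
  tr3 <- extract_strip_trace(pc3, "lacZ", lateral_strip(), "none")
  pk3 <- find_stripe_peaks(tr3, list(s1 = c(0.35, 0.55), s2 = c(0.75, 0.95)))
  expect_equal(pk3$ap_position, pk$ap_position)
})

test_that("flat traces yield boundary-flagged peaks at the trace value", {
  pc <- pointcloud("flat", "wild_type", 1,
                   data.frame(ap = rep(seq(0.005, 0.995, by = 0.01), 10),
                              dv = rep(runif(100), each = 10), lacZ = 2))
  tr <- extract_strip_trace(pc, "lacZ", full_strip(), "none")
  pk <- find_stripe_peaks(tr, list(s7 = c(0.78, 0.92)))
  expect_true(pk$boundary)
  expect_equal(pk$level, 2)
})

test_that("empty stripe windows give missing peaks", {
  pc <- grid_embryo()
  tr <- extract_strip_trace(pc, "lacZ", lateral_strip())
  tr$mean_intensity[tr$ap_bin_centers > 0.7] <- NA
  pk <- find_stripe_peaks(tr, list(s7 = c(0.78, 0.92)))
  expect_true(pk$missing)
  expect_true(is.na(pk$level))
})

test_that("ventral-lateral delta recovers planted ventral modulation", {
  # symmetric embryo: delta 0 (up to grid discretisation)
  pk0 <- ventral_lateral_delta(grid_embryo(vfactor = 0), "lacZ",
                               stripe_windows = list(`2` = c(0.35, 0.55)))
  expect_lt(abs(pk0$delta), 1e-9)  # deterministic grid: exact symmetry
  # planted repression 0.4
  pk <- ventral_lateral_delta(grid_embryo(vfactor = 0.4), "lacZ",
                              stripe_windows = list(`2` = c(0.35, 0.55)))
  expect_lt(abs(pk$delta - (-0.4)), 0.05)
  # planted ventral boost: positive delta
  pkb <- ventral_lateral_delta(grid_embryo(vfactor = -0.3), "lacZ",
                               stripe_windows = list(`2` = c(0.35, 0.55)))
  expect_gt(pkb$delta, 0.1)
})

test_that("deltas are invariant to a global intensity rescaling", {
  set.seed(52)
  sim <- simulate_embryo_cohort(embryo_sim_spec(
    n_nuclei = 3000, ventral_effect = c(`7` = 0.4)), 1, seed = 99)
  pc <- sim$cohort[[1]]
  pc2 <- pc
  pc2$nuclei$lacZ <- pc2$nuclei$lacZ * 7.3
  d1 <- ventral_lateral_delta(pc, "lacZ")
  d2 <- ventral_lateral_delta(pc2, "lacZ")
  expect_equal(d1$delta, d2$delta, tolerance = 1e-12)
})

test_that("co-stain normalization removes per-embryo intensity factors", {
  set.seed(53)
  sim <- simulate_embryo_cohort(
    embryo_sim_spec(n_nuclei = 3000, intensity_lnorm_sd = 0.4,
                    timepoints = 3), 16, seed = 530)
  res <- costain_normalize(sim$cohort, "lacZ", "hkb")
  kept <- res$embryos[!res$embryos$dropped, ]
  # recovered scales track the planted gains
  truth <- sim$truth[match(kept$embryo_id, sim$truth$embryo_id), ]
  expect_gt(cor(kept$scale, truth$gain), 0.99)
  lv7 <- res$levels[res$levels$stripe_id == "7", ]
  raw_cv <- sd(lv7$raw_level) / mean(lv7$raw_level)
  norm_cv <- sd(lv7$normalized_level) / mean(lv7$normalized_level)
  expect_lt(norm_cv, raw_cv / 2)
  expect_gt(res$correlation$r, 0.9)
  expect_lt(res$correlation$pvalue, 0.05)
})

test_that("a 10x co-stain outlier embryo is dropped by the MAD rule", {
  set.seed(54)
  sim <- simulate_embryo_cohort(
    embryo_sim_spec(n_nuclei = 2000, intensity_lnorm_sd = 0.2,
                    timepoints = 3), 12, seed = 540)
  out <- sim$cohort[[5]]
  out$nuclei$hkb <- out$nuclei$hkb * 10
  cohort <- sim$cohort
  cohort[[5]] <- out
  res <- suppressWarnings(costain_normalize(cohort, "lacZ", "hkb"))
  expect_true(res$embryos$dropped[5])
  expect_equal(res$embryos$reason[5], "costain_outlier")
  expect_false(any(res$embryos$dropped[-5]))
})

test_that("single-embryo normalization is a plain division", {
  pc <- grid_embryo()
  pc$nuclei$lacZ <- pc$nuclei$lacZ * 0.8
  pc$nuclei$hkb <- ifelse(pc$nuclei$ap < 0.1, 2, 0)
  res <- costain_normalize(list(pc), "lacZ", "hkb",
                           stripe_windows = list(`2` = c(0.35, 0.55)))
  expect_equal(res$levels$scale, 2)
  expect_equal(res$levels$normalized_level,
               res$levels$raw_level / 2)
})

test_that("mann-whitney U and exact p match hand enumeration", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$pvalue, 2 / 6)  # 6 rank assignments, doubled tail
  expect_true(res$exact)
  # identical multisets: p = 1 under the exact method
  expect_equal(mann_whitney_u(c(5, 7, 9), c(5, 7, 9))$pvalue, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "at least one")
})

test_that("the normal approximation tracks the exact MWU distribution", {
  set.seed(55)
  # n_a * n_b = 441 > 400 forces the approximate path; compare with the
  # exact tail from R's Wilcoxon distribution (no ties by construction)
  for (i in 1:5) {
    a <- rnorm(21)
    b <- rnorm(21, mean = 0.3)
    res <- mann_whitney_u(a, b)
    expect_false(res$exact)
    exact_p <- 2 * min(pwilcox(res$U, 21, 21),
                       1 - pwilcox(res$U - 1, 21, 21))
    expect_lt(abs(res$pvalue - min(exact_p, 1)), 0.01)
  }
})
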