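test_that("plating efficiency from control wells", {
  pe <- plating_efficiency(rep(85, 8), 100)
  expect_equal(pe$pe, 0.85)
  expect_equal(pe$sem, 0)
  pe2 <- plating_efficiency(c(80, 90), 100)
  expect_equal(pe2$pe, 0.85)
  expect_equal(pe2$sem, 0.05)
  expect_error(plating_efficiency(integer(0)), "control")
  # simulation oracle: 16 Poisson wells at true PE 0.8
  set.seed(9)
  counts <- rpois(16, 80)
  est <- plating_efficiency(counts, 100)
  expect_lt(abs(est$pe - 0.8), 3 * est$sem)
})

test_that("survival fractions pool replicate wells across plates", {
  cond <- data.frame(column = 1:12, dose_Gy = seq(0, 5.5, length.out = 12),
                     let_keV_um = 1:12)
  mk <- function(val) plate_counts(matrix(val, 8, 12), 100, cond)
  # counts equal to seeded * PE give SF = 1 in every condition
  sf <- survival_fractions(list(mk(80), mk(80)), pe = 0.8)
  expect_equal(sf$sf, rep(1, 12))
  expect_equal(sf$n_wells, rep(16L, 12))
  expect_equal(sf$cells_eff, rep(80, 12))
  # generator round trip: known SF grid recovered within 3 sem
  truth <- c(0.268, 0.097)
  pts <- simulate_survival_experiment(truth[1], truth[2], c(0, 1, 2, 4),
                                      wells_per_dose = 64, seed = 21)
  expected <- exp(-truth[1] * pts$dose_Gy - truth[2] * pts$dose_Gy^2)
  expect_true(all(abs(pts$sf - expected) <= 3 * pmax(pts$sem, 1e-3)))
})

test_that("limit of detection is 1/(cells plated * PE) with strict-below removal", {
  expect_equal(lod_threshold(100, 0.8), 0.0125)
  pts <- data.frame(dose_Gy = c(0, 2, 4, 6),
                    sf = c(1, 0.2, 0.0125, 0.01))
  kept <- lod_filter(pts, 100, 0.8)
  expect_equal(kept$dose_Gy, c(0, 2, 4))      # boundary point retained
  above <- data.frame(dose_Gy = 0:2, sf = c(1, 0.5, 0.2))
  expect_identical(lod_filter(above, 100, 0.8), above)
  # a self-consistent zero-dose point always survives the filter
  expect_true(0 %in% lod_filter(data.frame(dose_Gy = c(0, 8), sf = c(0.98, 1e-4)),
                                100, 0.8)$dose_Gy)
})

test_that("noiseless LQ data are recovered to machine precision", {
  for (ab in list(c(0.2, 0.05), c(0.883, 0.956), c(0.05, 0), c(0, 0.1))) {
    pts <- noiseless_points(ab[1], ab[2])
    f <- fit_lq(pts, variance = "residual")
    expect_equal(f$alpha, ab[1], tolerance = 1e-6)
    expect_equal(f$beta, ab[2], tolerance = 1e-6)
  }
  expect_error(fit_lq(data.frame(dose_Gy = c(0, 1), sf = c(1, 0.5))),
               "insufficient")
})

test_that("weighted fit agrees with a brute-force grid search", {
  pts <- simulate_survival_experiment(0.3, 0.08, c(0, 1, 2, 4, 6), seed = 14)
  f <- fit_lq(pts)
  grid_a <- seq(0.1, 0.5, by = 0.002)
  grid_b <- seq(0.0, 0.2, by = 0.002)
  g <- expand.grid(a = grid_a, b = grid_b)
  ss <- mapply(wrss, g$a, g$b, MoreArgs = list(pts = pts))
  best <- g[which.min(ss), ]
  expect_lt(abs(f$alpha - best$a), 0.002)
  expect_lt(abs(f$beta - best$b), 0.002)
})

test_that("fit recovers simulated radiosensitivity within its errors", {
  truth <- c(0.268, 0.097)
  pts <- simulate_survival_experiment(truth[1], truth[2],
                                      recovery_doses(truth[1], truth[2]),
                                      seed = 6)
  f <- fit_lq(pts)
  expect_lt(abs(f$alpha - truth[1]), 2 * f$se_alpha)
  expect_lt(abs(f$beta - truth[2]), 2 * f$se_beta)
  expect_true(all(is.finite(diag(f$vcov))))
})

test_that("SF at dose reproduces the published SF2 scale", {
  expect_equal(sf_at_dose(lq_fit(0.268, 0.097), 2), 0.40, tolerance = 0.01)
  expect_equal(sf_at_dose(lq_fit(0.883, 0.956), 2), 0.0037, tolerance = 0.01)
  f <- lq_fit(0.3, 0.05)
  expect_identical(sf_at_dose(f, 0), 1)
  d <- seq(0, 8, by = 0.5)
  expect_true(all(diff(sf_at_dose(f, d)) < 0))
})

test_that("isoeffect dose inverts the survival curve", {
  # independent root-finding oracle on the photon reference
  f <- lq_fit(0.290, 0.083)
  oracle <- uniroot(function(d) sf_at_dose(f, d) - 0.10, c(0.1, 20),
                    tol = 1e-12)$root
  expect_equal(dose_at_sf(f, 0.10), oracle, tolerance = 1e-9)
  expect_equal(dose_at_sf(f, 0.10), 3.802, tolerance = 1e-3)
  # linear (beta = 0) closed form
  expect_equal(dose_at_sf(lq_fit(log(2), 0), 0.5), 1.0, tolerance = 1e-12)
  # round trips both ways
  expect_equal(sf_at_dose(f, dose_at_sf(f, 0.37)), 0.37, tolerance = 1e-9)
  set.seed(2)
  for (i in 1:50) {
    g <- lq_fit(runif(1, 0.01, 1), runif(1, 0, 1))
    s <- runif(1, 0.001, 0.99)
    expect_equal(sf_at_dose(g, dose_at_sf(g, s)), s, tolerance = 1e-9)
  }
  expect_error(dose_at_sf(f, 1), "\\(0, 1\\)")
  expect_error(dose_at_sf(lq_fit(0, 0), 0.1), "zero")
})

test_that("RBE reproduces the published isoeffect ratios", {
  h460_ph <- lq_fit(0.290, 0.083)
  expect_equal(rbe(h460_ph, lq_fit(0.883, 0.956))$rbe, 3.28, tolerance = 0.005)
  h1437_ph <- lq_fit(0.050, 0.041)
  expect_equal(rbe(h1437_ph, lq_fit(0.180, 0.095))$rbe, 1.70, tolerance = 0.005)
  self <- rbe(h460_ph, h460_ph)
  expect_equal(self$rbe, 1.0, tolerance = 1e-12)
  # reciprocal symmetry
  a <- lq_fit(0.2, 0.1, se_alpha = 0.03, se_beta = 0.02)
  b <- lq_fit(0.5, 0.3, se_alpha = 0.05, se_beta = 0.04)
  expect_equal(rbe(a, b)$rbe * rbe(b, a)$rbe, 1.0, tolerance = 1e-12)
  expect_gte(rbe(a, b)$sd, 0)
})

test_that("RBE uncertainty propagates the fit covariance", {
  # delta method cross-checked by Monte Carlo over the parameter sampling
  # distribution
  ref <- lq_fit(0.290, 0.083, se_alpha = 0.02, se_beta = 0.006)
  tst <- lq_fit(0.446, 0.341, se_alpha = 0.05, se_beta = 0.03,
                cov_ab = -0.001)
  r <- rbe(ref, tst)
  set.seed(31)
  n <- 20000
  ch <- chol(tst$vcov)
  ab_t <- cbind(0.446, 0.341) [rep(1, n), ] + matrix(rnorm(2 * n), n) %*% ch
  ab_r <- cbind(rnorm(n, 0.290, 0.02), rnorm(n, 0.083, 0.006))
  d10 <- function(a, b) (-a + sqrt(a^2 - 4 * b * log(0.1))) / (2 * b)
  sims <- d10(ab_r[, 1], ab_r[, 2]) / d10(ab_t[, 1], ab_t[, 2])
  expect_equal(r$sd, sd(sims), tolerance = 0.1)
  expect_equal(r$rbe, mean(sims), tolerance = 0.02)
})

test_that("extra sum-of-squares F test separates distinct curves only", {
  pts <- simulate_survival_experiment(0.268, 0.097, c(0, 1, 2, 4, 6), seed = 8)
  same <- compare_lq_ftest(pts, pts)
  expect_lt(same$f, 1e-8)
  expect_equal(same$p_value, 1, tolerance = 1e-8)
  # strongly different radiosensitivities are separated decisively
  lo <- simulate_survival_experiment(0.268, 0.097,
                                     recovery_doses(0.268, 0.097), seed = 12)
  hi <- simulate_survival_experiment(0.883, 0.956,
                                     recovery_doses(0.883, 0.956), seed = 13)
  diffr <- compare_lq_ftest(lo, hi)
  expect_lt(diffr$p_value, 1e-4)
  expect_gt(diffr$f, 0)
})

test_that("RBE-LET table mirrors the reporting format", {
  ph <- reference_photon_fit("H460")
  single <- rbe_let_table(list("0.9" = ph), ph)
  expect_equal(single$rbe, 1.0, tolerance = 1e-12)
  tab <- rbe_let_table(reference_proton_fits("H460"), ph)
  expect_equal(nrow(tab), 12)
  expect_equal(tab$let_keV_um,
               c(0.9, 1.2, 1.6, 1.8, 1.9, 2.3, 3.0, 5.1, 10.8, 15.2, 17.7, 19.0))
  expect_true(all(diff(tab$d10_Gy[9:12]) < 0))
  # a degenerate fit keeps its row with NA isoeffect cells
  tab2 <- rbe_let_table(list("1" = lq_fit(0, 0)), ph)
  expect_equal(nrow(tab2), 1)
  expect_true(is.na(tab2$rbe))
})
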