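test_that("generators are reproducible under a fixed seed", {
  beam <- beam_spec()
  cc <- column_conditions(beam, default_jig(beam))
  design <- experiment_design("H460")
  p1 <- simulate_plate(design, cc, 77, seed = 5)
  p2 <- simulate_plate(design, cc, 77, seed = 5)
  expect_identical(p1$counts, p2$counts)
  t1 <- simulate_tracks(distal_mixture_spec(500), seed = 5)
  t2 <- simulate_tracks(distal_mixture_spec(500), seed = 5)
  expect_identical(t1, t2)
  expect_identical(simulate_foci(2, 10, n_nuclei = 50, seed = 5),
                   simulate_foci(2, 10, n_nuclei = 50, seed = 5))
})

test_that("control plates scatter around seeded cells times plating efficiency", {
  beam <- beam_spec()
  cc <- column_conditions(beam, default_jig(beam))
  design <- experiment_design("H460")   # PE 0.8, 100 cells/well
  ctrl <- simulate_plate(design, cc, paintings = 0, seed = 17)
  m <- mean(ctrl$counts)
  sem <- sd(ctrl$counts) / sqrt(96)
  expect_lt(abs(m - 80), 3 * sem)
  expect_equal(ctrl$conditions$dose_Gy, rep(0, 12))
  # radioresistant limit: alpha = beta = 0 behaves like a control plate
  design0 <- experiment_design("H460")
  design0$lq_params$alpha[] <- 0
  design0$lq_params$beta[] <- 0
  flat <- simulate_plate(design0, cc, paintings = 77, seed = 18)
  expect_lt(abs(mean(flat$counts) - 80), 3 * sd(flat$counts) / sqrt(96))
})

test_that("well counts are Poisson (variance ~ mean)", {
  pts <- replicate(200, {
    p <- simulate_survival_experiment(0.3, 0.1, c(0, 2), wells_per_dose = 1,
                                      seeded_per_well = 100, pe = 0.8)
    p$sf * 80
  })
  for (row in 1:2) {
    counts <- pts[row, ]
    expect_lt(abs(var(counts) / mean(counts) - 1), 0.35)
  }
})

test_that("track spectra land where specified", {
  # delta spectrum: both averages equal the specified LET
  d <- score_let(simulate_tracks(list(type = "delta", n = 100, value = 10)))
  expect_equal(d$let_track, 10, tolerance = 1e-12)
  expect_equal(d$let_dose, 10, tolerance = 1e-12)
  # any spread spectrum puts the dose average above the track average
  for (spec in list(list(type = "uniform", n = 2000, min = 2, max = 30),
                    list(type = "lognormal", n = 2000, meanlog = 2, sdlog = 0.5),
                    distal_mixture_spec(2000))) {
    r <- score_let(simulate_tracks(spec, seed = 23))
    expect_gt(r$let_dose, r$let_track)
  }
  # the distal mixture spans 3-80 keV/um with dose-mean ~19
  ev <- simulate_tracks(distal_mixture_spec(2e5), seed = 29)
  ratio <- ev$epsilon_keV / ev$length_um
  expect_gte(min(ratio), 3)
  expect_lte(max(ratio), 80)
  expect_equal(score_let(ev)$let_dose, 19, tolerance = 0.1)
  expect_error(simulate_tracks(list(type = "uniform", n = 10, min = 5, max = 2)),
               "uniform")
})

test_that("focus counts follow the LET-dependent yield", {
  expect_true(all(simulate_foci(2, yield_per_Gy = 0, n_nuclei = 100) == 0))
  # calibrated anchor conditions are clearly separated
  lo <- simulate_foci(2.9, 4.6, n_nuclei = 200, seed = 41)
  hi <- simulate_foci(1.7, 17.3, n_nuclei = 200, seed = 42)
  expect_lt(abs(mean(lo) - 3.57), 0.5)
  expect_lt(abs(mean(hi) - 7.02), 0.6)
  expect_lt(wilcox.test(lo, hi)$p.value, 1e-4)
  # identical conditions are not: p-values spread over (0, 1)
  set.seed(43)
  ps <- replicate(60, {
    a <- simulate_foci(2, 10, n_nuclei = 50)
    b <- simulate_foci(2, 10, n_nuclei = 50)
    suppressWarnings(wilcox.test(a, b)$p.value)
  })
  expect_gt(mean(ps > 0.05), 0.8)
  expect_gt(median(ps), 0.2)
})

test_that("full pipeline recovers the generating radiosensitivities", {
  res <- run_pipeline(read_config(), seed = 77)
  truth <- reference_lq_params("H460")
  truth <- truth[truth$radiation == "proton", ]
  fitted <- res$fits
  # the measurable plateau/peak columns are fittable at these dose levels
  expect_gte(nrow(fitted), 6)
  # match fitted rows to generating parameters via column order
  cc <- res$conditions
  idx <- match(round(fitted$let_keV_um, 6), round(cc$let_d_keV_um, 6))
  z_a <- abs(fitted$alpha - truth$alpha[idx]) / fitted$se_alpha
  z_b <- abs(fitted$beta - truth$beta[idx]) / fitted$se_beta
  expect_lt(median(c(z_a, z_b)), 2.5)
  expect_gt(mean(c(z_a, z_b) < 3), 0.7)
  # photon reference recovered too
  ph <- res$photon_fit
  expect_lt(abs(ph$alpha - 0.290), 3 * ph$se_alpha)
  expect_lt(abs(ph$beta - 0.083), 3 * ph$se_beta)
})
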