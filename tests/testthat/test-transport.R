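test_that("range-energy law is invertible and monotone", {
  E <- c(0.5, 1, 5, 20, 50, 79.7, 150, 221.8)
  for (mat in list(water(), lucite())) {
    R <- range_from_energy(E, mat)
    expect_true(all(diff(R) > 0))
    expect_equal(energy_from_range(R, mat), E, tolerance = 1e-9)
  }
  # round trip at 50 MeV and the zero-range endpoint
  expect_equal(energy_from_range(range_from_energy(50), water()), 50,
               tolerance = 1e-9)
  expect_identical(energy_from_range(0), 0)
  expect_lt(range_from_energy(1e-9), 1e-12)
})

test_that("water range of the 79.7 MeV beam and the Lucite ratio match", {
  expect_equal(range_from_energy(79.7, water()), 5.107, tolerance = 2e-3)
  # ratio water/Lucite is energy independent and equals 4.8/4.1
  for (E in c(5, 79.7, 200)) {
    expect_equal(range_from_energy(E, water()) / range_from_energy(E, lucite()),
                 4.8 / 4.1, tolerance = 1e-12)
  }
})

test_that("invalid energies and ranges are rejected", {
  expect_error(range_from_energy(-1), "positive")
  expect_error(range_from_energy(0), "positive")
  expect_error(energy_from_range(-0.1), ">= 0")
  expect_error(stopping_power(0), "positive")
})

test_that("stopping power is the derivative of the range-energy law", {
  E <- seq(1, 80, by = 1)
  S_MeV_cm <- stopping_power(E) * 10  # keV/um -> MeV/cm
  expect_true(all(diff(S_MeV_cm) < 0))
  # integrating dE/S from E0 down to 0 reproduces the range
  E0 <- 79.7
  rng <- stats::integrate(function(e) 1 / (stopping_power(e) * 10), 0, E0,
                          rel.tol = 1e-9)$value
  expect_equal(rng, range_from_energy(E0), tolerance = 1e-3)
  # entrance LET scale of the therapeutic beam, ~0.9 keV/um
  expect_equal(stopping_power(79.7), 0.9, tolerance = 0.2)
})

test_that("water-equivalent thickness is additive", {
  expect_identical(water_equivalent_thickness(list()), 0)
  expect_equal(water_equivalent_thickness(slab(lucite(), 1)), 4.8 / 4.1,
               tolerance = 1e-12)
  films <- replicate(3, slab(film(), 0.0268), simplify = FALSE)
  expect_equal(water_equivalent_thickness(films), 0.09413, tolerance = 1e-4)
  # additivity over random stacks
  set.seed(5)
  for (i in 1:20) {
    th <- runif(4, 0, 2)
    mats <- list(water(), lucite(), well_plate_plastic(), film())
    stack <- lapply(1:4, function(k) slab(mats[[k]], th[k]))
    expect_equal(water_equivalent_thickness(stack),
                 sum(vapply(stack, water_equivalent_thickness, numeric(1))),
                 tolerance = 1e-12)
  }
})

test_that("narrow-spread Bragg peak sits at the analytic range", {
  beam <- beam_spec(energy_spread_sigma_MeV = 0.05, range_straggling_frac = 0)
  grid <- seq(4.5, 4.9, by = 0.004)
  prof <- bragg_depth_dose(beam, depth_grid_cm = grid)
  z_peak <- prof$depth_cm[which.max(prof$dose)]
  expect_lt(abs(z_peak - beam$range_water_cm), 0.008)
})

test_that("peak-to-entrance ratio decreases with energy spread", {
  ratios <- vapply(c(0.3, 0.6, 0.9, 1.2), function(sig) {
    beam <- beam_spec(energy_spread_sigma_MeV = sig, range_straggling_frac = 0)
    grid <- sort(unique(c(seq(0, 5.2, by = 0.02), seq(4.3, 5.2, by = 0.002))))
    prof <- bragg_depth_dose(beam, depth_grid_cm = grid)
    max(prof$dose) / prof$dose[1]
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("depth profile is unimodal with LET_d rising through the peak", {
  prof <- bragg_depth_dose(beam_spec())
  d <- prof$dose
  ip <- which.max(d)
  expect_gt(ip, 1)
  expect_lt(ip, nrow(prof))
  expect_true(all(diff(d[1:ip]) > 0))
  expect_true(all(diff(d[ip:length(d)]) < 0))
  ok <- !is.na(prof$let_d_keV_um)
  expect_true(all(diff(prof$let_d_keV_um[ok]) > 0))
  # narrow-spectrum limit at the entrance: LET_d ~ stopping power
  beam <- beam_spec()
  expect_equal(prof$let_d_keV_um[1],
               stopping_power(beam$effective_energy_MeV),
               tolerance = 0.05)
  expect_error(bragg_depth_dose(beam, depth_grid_cm = c(1, 0.5)), "increasing")
})

test_that("column conditions reproduce the plate-mapping design", {
  beam <- beam_spec()
  cc <- column_conditions(beam, default_jig(beam))
  expect_equal(cc$dose_rel[1], 1.0, tolerance = 1e-12)
  expect_equal(cc$dose_cGy_per_painting[1], 2.6, tolerance = 1e-12)
  expect_true(all(diff(cc$let_d_keV_um) > 0))
  expect_equal(which.max(cc$dose_rel), 9)
  expect_equal(max(cc$dose_rel), 5.5, tolerance = 0.02)
  expect_false(any(cc$beyond_range))
})

test_that("columns beyond the beam range are flagged, not an error", {
  beam <- beam_spec()
  jig <- jig_geometry(seq(3.9, 4.6, length.out = 12))
  cc <- column_conditions(beam, jig)
  expect_true(any(cc$beyond_range))
  expect_true(all(cc$dose_rel[cc$beyond_range] == 0))
  expect_false(cc$beyond_range[1])
})

test_that("jig design hits requested depths and LET targets", {
  beam <- beam_spec()
  # a shallow single target needs no step
  j0 <- design_jig(beam, 0.05, type = "depth")
  expect_equal(j0$step_thickness_cm[1], 0)
  # monotone depth targets give monotone thicknesses
  jd <- design_jig(beam, seq(0.5, 4.7, length.out = 12), type = "depth")
  expect_true(all(diff(jd$step_thickness_cm) >= 0))
  # LET targets round-trip through column_conditions within 10%
  lets <- c(1.2, 1.9, 3.0, 5.1, 15.2, 17.7, 19.0)
  jl <- design_jig(beam, lets, type = "let")
  cc <- column_conditions(beam, jl)
  expect_equal(cc$let_d_keV_um[seq_along(lets)], lets, tolerance = 0.1)
  expect_error(design_jig(beam, 10, type = "depth"), "unreachable")
  expect_error(design_jig(beam, 100, type = "let"), "reachable")
})

test_that("scan field matches brute-force spot summation and is uniform", {
  beam <- beam_spec()
  s <- beam$spot_fwhm_cm / (2 * sqrt(2 * log(2)))
  # single spot: half maximum at r = FWHM/2
  expect_equal(scan_field_dose(beam$spot_fwhm_cm / 2, 0, beam, 0),
               0.5 * scan_field_dose(0, 0, beam, 0), tolerance = 1e-12)
  # brute-force double sum oracle at a few points
  pos <- seq(-10, 10)
  brute <- function(x, y) {
    tot <- 0
    for (i in pos) for (j in pos) {
      tot <- tot + exp(-((x - i)^2 + (y - j)^2) / (2 * s^2))
    }
    tot
  }
  for (pt in list(c(0, 0), c(1.3, -2.1), c(3.6, 3.6))) {
    expect_equal(scan_field_dose(pt[1], pt[2], beam, 10), brute(pt[1], pt[2]),
                 tolerance = 1e-10)
  }
  # symmetry and central-span uniformity over the 7.2 cm column extent
  expect_equal(scan_field_dose(2.5, 1, beam), scan_field_dose(-2.5, -1, beam),
               tolerance = 1e-12)
  span <- seq(-3.6, 3.6, by = 0.05)
  d <- scan_field_dose(span, 0, beam)
  expect_gte(min(d) / max(d), 0.99)
})

test_that("painting counts follow the monitor-unit calibration", {
  beam <- beam_spec()
  p0 <- paintings_for_dose(0, beam)
  expect_identical(p0$paintings, 0)
  expect_identical(p0$delivered_Gy, 0)
  p2 <- paintings_for_dose(2.0, beam)
  expect_equal(p2$paintings, 77)
  expect_equal(p2$delivered_Gy, 2.002, tolerance = 1e-12)
  expect_equal(paintings_for_dose(0.026, beam)$monitor_units, 17.64,
               tolerance = 1e-12)
})
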