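#' Proton range from energy (Bragg-Kleeman law)
#'
#' R = a E^p in the given material, with the material coefficient tied
#' to water through the water-equivalent ratio so that
#' `range_from_energy(E, water()) / range_from_energy(E, lucite())`
#' equals the WER of Lucite at every energy.
#'
#' @param energy_MeV Proton kinetic energy, MeV (vectorised, > 0).
#' @param material A [material()]; default water.
#' @return Range in cm of the material.
#' @export
range_from_energy <- function(energy_MeV, material = water()) {
  stopifnot(inherits(material, "material"))
  if (any(!is.finite(energy_MeV)) || any(energy_MeV <= 0)) {
    stop("energy must be positive")
  }
  material$a * energy_MeV^material$p
}

#' Proton energy from residual range
#'
#' Exact inverse of [range_from_energy()]; returns 0 for zero range.
#'
#' @param range_cm Residual range in the material, cm (>= 0).
#' @inheritParams range_from_energy
#' @return Energy in MeV.
#' @export
energy_from_range <- function(range_cm, material = water()) {
  stopifnot(inherits(material, "material"))
  if (any(!is.finite(range_cm)) || any(range_cm < 0)) {
    stop("residual range must be >= 0")
  }
  (range_cm / material$a)^(1 / material$p)
}

#' Stopping power of a monoenergetic proton beam
#'
#' dE/dx obtained by differentiating the range-energy law:
#' S(E) = E^(1-p) / (a p) in MeV/cm, returned in keV/um. For a narrow
#' spectrum this equals the unrestricted track LET.
#'
#' @inheritParams range_from_energy
#' @return Stopping power in keV/um.
#' @export
stopping_power <- function(energy_MeV, material = water()) {
  stopifnot(inherits(material, "material"))
  if (any(!is.finite(energy_MeV)) || any(energy_MeV <= 0)) {
    stop("energy must be positive")
  }
  # 1 MeV/cm = 0.1 keV/um
  0.1 * energy_MeV^(1 - material$p) / (material$a * material$p)
}

#' Water-equivalent thickness of a slab stack
#'
#' WET is additive over slabs: sum of thickness times WER.
#'
#' @param stack A list of [slab()] objects (possibly empty), or a
#'   single slab.
#' @return WET in cm of water.
#' @export
water_equivalent_thickness <- function(stack) {
  if (inherits(stack, "slab")) stack <- list(stack)
  if (length(stack) == 0L) return(0)
  sum(vapply(stack, function(s) {
    stopifnot(inherits(s, "slab"))
    s$thickness_cm * s$material$wer
  }, numeric(1)))
}

# --- internal depth-dose / depth-LET engine -------------------------------
#
# The residual-range distribution of the beam at the phantom surface is
# Gaussian with mean R0 and standard deviation sigma (energy spread
# mapped to range spread, combined in quadrature with range
# straggling). At depth z the local dose is the mean stopping power of
# the surviving spectrum and LET_d the dose-weighted mean:
#   dose(z)  = int S(R - z)   phi(R; R0, sigma) dR   over R > z
#   let_d(z) = int S(R - z)^2 phi dR / dose(z)
# With S(u) = C u^q, q = (1-p)/p < 0, the integrable singularity at
# u = R - z = 0 is removed exactly by the substitutions u = t^p (first
# moment) and u = s^m, m = p/(2-p) (second moment), after which the
# integrands are smooth and a midpoint rule converges quickly. Node
# counts scale with R0/sigma so that narrow spectra stay resolved.

.range_sigma_water <- function(beam) {
  w <- water()
  E <- beam$effective_energy_MeV
  drde <- w$a * w$p * E^(w$p - 1)
  sqrt((drde * beam$energy_spread_sigma_MeV)^2 +
         (beam$range_straggling_frac * beam$range_water_cm)^2)
}

.dose_let_engine <- function(z, R0, sigma, a, p, nodes_per_width = 5) {
  q <- (1 - p) / p
  C <- 0.1 * a^(-q - 1) / p            # S(u) = C u^q, keV/um
  m <- p / (2 - p)
  Rmax <- R0 + 6 * sigma
  n1 <- min(30000L, max(500L, ceiling(nodes_per_width * p * Rmax / sigma)))
  n2 <- min(60000L, max(500L, ceiling(nodes_per_width * m * Rmax / sigma)))
  x1 <- (seq_len(n1) - 0.5) / n1
  x2 <- (seq_len(n2) - 0.5) / n2
  dose <- numeric(length(z))
  letd <- rep(NA_real_, length(z))
  for (i in seq_along(z)) {
    zz <- z[i]
    if (zz >= Rmax) next
    T1 <- (Rmax - zz)^(1 / p)
    I1 <- C * p * T1 * mean(stats::dnorm(zz + (x1 * T1)^p, R0, sigma))
    T2 <- (Rmax - zz)^(1 / m)
    I2 <- C^2 * m * T2 * mean(stats::dnorm(zz + (x2 * T2)^m, R0, sigma))
    dose[i] <- I1
    if (I1 > 0) letd[i] <- I2 / I1
  }
  list(dose = dose, let_d = letd)
}

#' Pristine Bragg depth-dose and depth-LET profile
#'
#' Computes the analytic depth-dose curve of the beam in a uniform
#' material together with the dose-averaged LET at each depth. The
#' beam's residual-range distribution is Gaussian (energy spread mapped
#' through dR/dE, combined with range straggling); dose is the mean
#' stopping power of the surviving spectrum and LET_d its dose-weighted
#' mean. Dose is in arbitrary units (normalise as needed), LET_d in
#' keV/um.
#'
#' @param beam A [beam_spec()].
#' @param material A [material()]; default water.
#' @param depth_grid_cm Increasing vector of depths, cm. Defaults to a
#'   grid reaching past the distal falloff with 100 um steps, refined
#'   to 10 um within half a centimetre of the peak.
#' @return A data frame of class `depth_profile` with columns `depth_cm`,
#'   `dose` (relative) and `let_d_keV_um`.
#' @export
bragg_depth_dose <- function(beam, material = water(), depth_grid_cm = NULL) {
  stopifnot(inherits(beam, "beam_spec"), inherits(material, "material"))
  R0 <- beam$range_water_cm / material$wer
  sigma <- .range_sigma_water(beam) / material$wer
  if (is.null(depth_grid_cm)) {
    zmax <- R0 + 5 * sigma
    coarse <- seq(0, zmax, by = 0.01)
    fine <- seq(max(0, R0 - 0.5), zmax, by = 0.001)
    depth_grid_cm <- sort(unique(c(coarse, fine)))
  }
  if (any(diff(depth_grid_cm) <= 0)) stop("depth grid must be strictly increasing")
  prof <- .dose_let_engine(depth_grid_cm, R0, sigma, material$a, material$p)
  structure(
    data.frame(depth_cm = depth_grid_cm, dose = prof$dose,
               let_d_keV_um = prof$let_d),
    class = c("depth_profile", "data.frame"),
    beam = beam, material = material$name, R0 = R0, sigma = sigma
  )
}

# cached default water profile per beam (the jig design and column
# evaluation both interrogate it)
.braggmap_cache <- new.env(parent = emptyenv())

.water_profile <- function(beam) {
  key <- paste(c("prof", unlist(beam[sapply(beam, is.numeric)])), collapse = "|")
  if (!is.null(.braggmap_cache[[key]])) return(.braggmap_cache[[key]])
  prof <- bragg_depth_dose(beam)
  .braggmap_cache[[key]] <- prof
  prof
}

#' Predicted dose and LET per plate column
#'
#' Evaluates the cell-layer dose and dose-averaged LET for each of the
#' 12 columns of a jig: the water-equivalent depth of each column's
#' cell layer (step + films + plate bottom + half the cell layer) is
#' looked up on the beam's depth-dose and depth-LET curves. Doses are
#' normalised to column 1 and converted to absolute cGy per painting
#' with the delivery calibration. Columns whose stack exceeds the beam
#' range are flagged `beyond_range` and given zero dose rather than
#' raising an error.
#'
#' @param beam A [beam_spec()].
#' @param jig A [jig_geometry()].
#' @return A data frame with one row per column: `column`, `step_cm`,
#'   `wet_cm`, `dose_rel` (column 1 = 1), `dose_cGy_per_painting`,
#'   `let_d_keV_um`, `beyond_range`.
#' @export
column_conditions <- function(beam, jig) {
  stopifnot(inherits(beam, "beam_spec"), inherits(jig, "jig_geometry"))
  wets <- vapply(1:12, function(cc) water_equivalent_thickness(column_stack(jig, cc)),
                 numeric(1))
  depths <- wets + jig$cell_layer_um * 1e-4 / 2    # mid cell layer, ~water
  R0 <- beam$range_water_cm
  sigma <- .range_sigma_water(beam)
  prof <- .dose_let_engine(depths, R0, sigma, water()$a, water()$p)
  beyond <- prof$dose <= 0
  if (beyond[1] || prof$dose[1] <= 0) {
    stop("beam range shorter than the column-1 stack; no entrance dose to normalise to")
  }
  dose_rel <- prof$dose / prof$dose[1]
  data.frame(
    column = 1:12,
    step_cm = jig$step_thickness_cm,
    wet_cm = wets,
    dose_rel = dose_rel,
    dose_cGy_per_painting = beam$dose_per_painting_cGy * dose_rel,
    let_d_keV_um = prof$let_d,
    beyond_range = beyond
  )
}

#' Design jig step thicknesses for target depths or LET values
#'
#' Chooses the 12 Lucite step thicknesses so that each column's cell
#' layer sits at a requested water-equivalent depth, or at the depth
#' where the beam's dose-averaged LET reaches a requested value
#' (`type = "let"`; LET_d increases monotonically with depth so the
#' inversion is unique). Targets shallower than the fixed films + plate
#' bottom offset get a zero-thickness step; targets beyond the beam's
#' distal extent raise an error.
#'
#' @param beam A [beam_spec()].
#' @param targets Increasing numeric vector (at most 12) of target
#'   depths in cm water (`type = "depth"`) or target LET_d in keV/um
#'   (`type = "let"`).
#' @param type Interpretation of `targets`.
#' @param n_films,film_thickness_um,plate_bottom_cm,cell_layer_um Fixed
#'   stack parameters, passed to [jig_geometry()].
#' @return A [jig_geometry()] whose step count is padded to 12 by
#'   repeating the last designed thickness when fewer targets are given.
#' @export
design_jig <- function(beam, targets, type = c("let", "depth"),
                       n_films = 3, film_thickness_um = 268,
                       plate_bottom_cm = 0.1, cell_layer_um = 5) {
  type <- match.arg(type)
  stopifnot(inherits(beam, "beam_spec"))
  if (length(targets) > 12L) stop("at most 12 targets (one per column)")
  if (any(diff(targets) <= 0)) stop("targets must be strictly increasing")
  offset <- n_films * film_thickness_um * 1e-4 * film()$wer +
    plate_bottom_cm * well_plate_plastic()$wer + cell_layer_um * 1e-4 / 2
  if (type == "depth") {
    zmax <- beam$range_water_cm + 5 * .range_sigma_water(beam)
    if (any(targets > zmax)) stop("target depth beyond the beam range is unreachable")
    depths <- targets
  } else {
    prof <- .water_profile(beam)
    ok <- !is.na(prof$let_d_keV_um) & prof$dose > 0
    zz <- prof$depth_cm[ok]
    ll <- prof$let_d_keV_um[ok]
    if (any(targets > max(ll)) || any(targets < min(ll))) {
      stop("target LET outside the range reachable along the Bragg curve")
    }
    depths <- stats::approx(ll, zz, xout = targets, ties = "ordered")$y
  }
  steps <- pmax(0, depths - offset) / lucite()$wer
  if (length(steps) < 12L) steps <- c(steps, rep(steps[length(steps)], 12L - length(steps)))
  jig_geometry(cummax(steps), n_films = n_films,
               film_thickness_um = film_thickness_um,
               plate_bottom_cm = plate_bottom_cm, cell_layer_um = cell_layer_um)
}

#' Default jig reproducing the mapping experiment's sampling strategy
#'
#' Column 1 has no step (entrance plateau); columns 2-8 are placed at
#' dose-averaged LET targets 1.2, 1.6, 1.8, 1.9, 2.3, 3.0 and
#' 5.1 keV/um; column 9 is pinned to the Bragg-peak depth (with the
#' three-film offset this is the column the peak was aligned to);
#' columns 10-12 sample the distal falloff at LET targets 15.2, 17.7
#' and 19.0 keV/um. Step thicknesses therefore grow in large steps
#' proximally and increasingly fine increments toward the end of range.
#' The exact thicknesses are reverse-engineered from the published
#' per-column LET values, not manufacturing drawings.
#'
#' @param beam A [beam_spec()].
#' @return A [jig_geometry()].
#' @export
default_jig <- function(beam = beam_spec()) {
  key <- paste(c("jig", unlist(beam[sapply(beam, is.numeric)])), collapse = "|")
  if (!is.null(.braggmap_cache[[key]])) return(.braggmap_cache[[key]])
  prof <- .water_profile(beam)
  z_peak <- prof$depth_cm[which.max(prof$dose)]
  let_lo <- c(1.2, 1.6, 1.8, 1.9, 2.3, 3.0, 5.1)
  let_hi <- c(15.2, 17.7, 19.0)
  jig_lo <- design_jig(beam, let_lo, type = "let")
  jig_hi <- design_jig(beam, let_hi, type = "let")
  offset <- water_equivalent_thickness(column_stack(jig_lo, 1)) -
    jig_lo$step_thickness_cm[1] * lucite()$wer +
    jig_lo$cell_layer_um * 1e-4 / 2
  step_peak <- (z_peak - offset) / lucite()$wer
  steps <- c(0, jig_lo$step_thickness_cm[1:7], step_peak,
             jig_hi$step_thickness_cm[1:3])
  jig <- jig_geometry(cummax(steps))
  .braggmap_cache[[key]] <- jig
  jig
}

#' Scanned-field dose from Gaussian spot superposition
#'
#' Relative dose at (x, y) in the isocentre plane from a square scan
#' pattern of (2 g + 1)^2 spots spaced `spot_spacing_cm` apart, each a
#' 2-D Gaussian of the beam's spot FWHM. With the default beam
#' (g = 10: 441 spots forming a 20 x 20 cm field) the central region is
#' uniform to better than 1% over the 7.2 cm span of a plate column.
#'
#' @param x,y Coordinates in cm (vectorised; recycled to a common
#'   length).
#' @param beam A [beam_spec()].
#' @param grid_half_count g >= 0, the number of spots on each side of
#'   the central spot.
#' @return Relative dose (single-spot centre = 1).
#' @export
scan_field_dose <- function(x, y, beam = beam_spec(), grid_half_count = 10) {
  stopifnot(inherits(beam, "beam_spec"), grid_half_count >= 0)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  s <- beam$spot_fwhm_cm / (2 * sqrt(2 * log(2)))
  pos <- seq(-grid_half_count, grid_half_count) * beam$spot_spacing_cm
  # the square grid factorises: sum_ij fx_i fy_j = (sum_i fx_i)(sum_j fy_j)
  gx <- outer(x, pos, function(a, b) exp(-(a - b)^2 / (2 * s^2)))
  gy <- outer(y, pos, function(a, b) exp(-(a - b)^2 / (2 * s^2)))
  rowSums(gx) * rowSums(gy)
}

#' Repaintings needed for a target entrance dose
#'
#' Dose is delivered in integer repaintings of the scan pattern, each
#' depositing a fixed calibrated dose at column 1; relative column
#' doses are unchanged by the painting count.
#'
#' @param target_dose_Gy Desired column-1 dose in Gy (>= 0).
#' @param beam A [beam_spec()].
#' @return A list with `paintings` (nearest integer), `delivered_Gy`
#'   (exact delivered column-1 dose) and `monitor_units`.
#' @export
paintings_for_dose <- function(target_dose_Gy, beam = beam_spec()) {
  stopifnot(inherits(beam, "beam_spec"))
  if (any(target_dose_Gy < 0)) stop("target dose must be >= 0")
  per <- beam$dose_per_painting_cGy / 100
  n <- round(target_dose_Gy / per)
  list(paintings = n, delivered_Gy = n * per,
       monitor_units = n * beam$mu_per_painting)
}
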