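#' Define an attenuator material
#'
#' A material is characterised by its density and its water-equivalent
#' ratio (WER), the centimetres of water that degrade a proton beam as
#' much as one centimetre of the material. The Bragg-Kleeman
#' range-energy law R = a E^p is carried per material, with the
#' material coefficient derived from the water coefficient through the
#' WER so that range ratios between materials are energy-independent.
#'
#' @param name Material name.
#' @param density Mass density in g/cm^3. Must be positive.
#' @param wer Water-equivalent ratio (cm water per cm material). Must be
#'   positive.
#' @param a_water Bragg-Kleeman coefficient for water, cm/MeV^p.
#' @param p Bragg-Kleeman exponent (dimensionless, 1 < p < 2).
#' @return An object of class `material`.
#' @seealso [water()], [lucite()], [well_plate_plastic()]
#' @export
material <- function(name, density, wer, a_water = 0.0022, p = 1.77) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(density) || density <= 0) stop("density must be > 0")
  if (!is.numeric(wer) || wer <= 0) stop("water-equivalent ratio must be > 0")
  if (!is.numeric(a_water) || a_water <= 0) stop("range coefficient must be > 0")
  if (!is.numeric(p) || p <= 1 || p >= 2) stop("range exponent must satisfy 1 < p < 2")
  structure(
    list(name = name, density = density, wer = wer,
         a = a_water / wer, p = p, a_water = a_water),
    class = "material"
  )
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s: density %.3f g/cm3, WER %.4f, R = %.3g E^%.2f cm\n",
              x$name, x$density, x$wer, x$a, x$p))
  invisible(x)
}

#' Standard materials
#'
#' `water()` is the reference medium. `lucite()` (PMMA, the jig
#' material) takes its WER from the printed beam ranges: 4.8 cm in
#' water versus 4.1 cm in Lucite for the same beam. `film()` treats
#' radiochromic film as Lucite-equivalent, since only its
#' water-equivalent thickness matters here. `well_plate_plastic()`
#' models the polystyrene plate bottom, with the WER scaled from Lucite
#' by the density ratio 1.09/1.19.
#'
#' @return A `material` object.
#' @rdname standard-materials
#' @export
water <- function() material("water", density = 1.0, wer = 1.0)

#' @rdname standard-materials
#' @export
lucite <- function() material("lucite", density = 1.19, wer = 4.8 / 4.1)

#' @rdname standard-materials
#' @export
film <- function() material("film", density = 1.19, wer = 4.8 / 4.1)

#' @rdname standard-materials
#' @export
well_plate_plastic <- function() {
  material("well-plate plastic", density = 1.09, wer = (4.8 / 4.1) * 1.09 / 1.19)
}

#' A slab of material
#'
#' @param material A [material()] object.
#' @param thickness_cm Slab thickness in cm (non-negative).
#' @return An object of class `slab`.
#' @export
slab <- function(material, thickness_cm) {
  stopifnot(inherits(material, "material"))
  if (!is.numeric(thickness_cm) || thickness_cm < 0) {
    stop("slab thickness must be >= 0")
  }
  structure(list(material = material, thickness_cm = thickness_cm),
            class = "slab")
}

#' Specify the scanned proton beam
#'
#' Captures the delivery parameters of the monoenergetic scanned beam:
#' nominal energy, calibrated range in water (from which the effective
#' energy at the jig surface is derived through the range-energy law),
#' energy spread, spot size and spacing, and the monitor-unit
#' calibration that delivers a fixed entrance dose per repainting of
#' the scan pattern.
#'
#' The effective energy is the energy whose Bragg-Kleeman range equals
#' `range_water_cm`; it is slightly below the nominal accelerator
#' energy because of upstream material in the nozzle. The energy
#' spread default is calibrated so that the modelled peak-to-entrance
#' dose ratio across the plate columns is about 5.5; it is a
#' configuration value, not a prediction.
#'
#' @param nominal_energy_MeV Accelerator energy setting, MeV.
#' @param range_water_cm Beam range in water, cm.
#' @param energy_spread_sigma_MeV Gaussian energy spread (1 sigma), MeV.
#' @param range_straggling_frac Range straggling as a fraction of the
#'   range (combined in quadrature with the energy-spread term).
#' @param spot_fwhm_cm Spot full width at half maximum in air at
#'   isocentre, cm. The delivery report states 3.3 cm; 3.5 cm is also
#'   quoted for the uniformity measurement and may be set here.
#' @param spot_spacing_cm Scan-pattern spot spacing, cm.
#' @param dose_per_painting_cGy Dose delivered to the column-1 cell
#'   layer per repainting, cGy.
#' @param mu_per_painting Monitor units per repainting.
#' @return An object of class `beam_spec`.
#' @export
beam_spec <- function(nominal_energy_MeV = 79.7,
                      range_water_cm = 4.8,
                      energy_spread_sigma_MeV = 0.545,
                      range_straggling_frac = 0.012,
                      spot_fwhm_cm = 3.3,
                      spot_spacing_cm = 1,
                      dose_per_painting_cGy = 2.6,
                      mu_per_painting = 17.64) {
  vals <- c(nominal_energy_MeV, range_water_cm, energy_spread_sigma_MeV,
            spot_fwhm_cm, spot_spacing_cm, dose_per_painting_cGy,
            mu_per_painting)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all beam parameters must be positive and finite")
  }
  if (range_straggling_frac < 0) stop("range straggling fraction must be >= 0")
  w <- water()
  effective_energy <- (range_water_cm / w$a)^(1 / w$p)
  if (effective_energy > nominal_energy_MeV + 1e-9) {
    stop("calibrated range implies an effective energy above the nominal energy")
  }
  structure(
    list(nominal_energy_MeV = nominal_energy_MeV,
         effective_energy_MeV = effective_energy,
         range_water_cm = range_water_cm,
         energy_spread_sigma_MeV = energy_spread_sigma_MeV,
         range_straggling_frac = range_straggling_frac,
         spot_fwhm_cm = spot_fwhm_cm,
         spot_spacing_cm = spot_spacing_cm,
         dose_per_painting_cGy = dose_per_painting_cGy,
         mu_per_painting = mu_per_painting),
    class = "beam_spec"
  )
}

#' @export
print.beam_spec <- function(x, ...) {
  cat(sprintf(
    "<beam_spec> %.1f MeV scanned beam (effective %.2f MeV, range %.2f cm water)\n",
    x$nominal_energy_MeV, x$effective_energy_MeV, x$range_water_cm))
  cat(sprintf("  sigma_E %.3f MeV, straggling %.1f%% of range\n",
              x$energy_spread_sigma_MeV, 100 * x$range_straggling_frac))
  cat(sprintf("  spot FWHM %.1f cm @ %.1f cm spacing; %.2f cGy (%.2f MU) per painting\n",
              x$spot_fwhm_cm, x$spot_spacing_cm,
              x$dose_per_painting_cGy, x$mu_per_painting))
  invisible(x)
}

#' Twelve-column range-shifter jig geometry
#'
#' The jig is an ordered stack per plate column: a Lucite step of
#' column-specific thickness, a fixed number of films, and the plate
#' bottom, with the cell monolayer scored on top. Step thicknesses must
#' be non-decreasing with column index (thicker steps push the cell
#' layer deeper along the Bragg curve).
#'
#' @param step_thickness_cm Numeric vector of 12 step thicknesses, cm,
#'   non-decreasing.
#' @param n_films Number of films in the stack (default 3, the number
#'   needed to centre the Bragg peak on column 9).
#' @param film_thickness_um Thickness of each film, micrometres.
#' @param plate_bottom_cm Well-plate bottom thickness, cm.
#' @param cell_layer_um Thickness of the scored cell layer, micrometres.
#' @return An object of class `jig_geometry`.
#' @export
jig_geometry <- function(step_thickness_cm,
                         n_films = 3,
                         film_thickness_um = 268,
                         plate_bottom_cm = 0.1,
                         cell_layer_um = 5) {
  if (length(step_thickness_cm) != 12L) {
    stop("a jig has exactly 12 columns of steps")
  }
  if (any(step_thickness_cm < 0)) stop("step thicknesses must be >= 0")
  if (any(diff(step_thickness_cm) < -1e-9)) {
    stop("step thicknesses must be non-decreasing with column index")
  }
  if (cell_layer_um <= 0) stop("cell layer thickness must be > 0")
  structure(
    list(step_thickness_cm = as.numeric(step_thickness_cm),
         n_films = as.integer(n_films),
         film_thickness_um = film_thickness_um,
         plate_bottom_cm = plate_bottom_cm,
         cell_layer_um = cell_layer_um,
         step_material = lucite(),
         film_material = film(),
         plate_material = well_plate_plastic()),
    class = "jig_geometry"
  )
}

#' @export
print.jig_geometry <- function(x, ...) {
  cat("<jig_geometry> 12-column range shifter\n")
  cat("  steps (cm):", paste(sprintf("%.3f", x$step_thickness_cm), collapse = " "), "\n")
  cat(sprintf("  %d film(s) x %.0f um + %.2f cm plate bottom; cell layer %.0f um\n",
              x$n_films, x$film_thickness_um, x$plate_bottom_cm, x$cell_layer_um))
  invisible(x)
}

#' Attenuator stack for one jig column
#'
#' @param jig A [jig_geometry()].
#' @param column Column index, 1-12.
#' @return A list of [slab()] objects in beam order (step, films,
#'   plate bottom).
#' @export
column_stack <- function(jig, column) {
  stopifnot(inherits(jig, "jig_geometry"), column %in% 1:12)
  stack <- list(slab(jig$step_material, jig$step_thickness_cm[column]))
  for (i in seq_len(jig$n_films)) {
    stack <- c(stack, list(slab(jig$film_material, jig$film_thickness_um * 1e-4)))
  }
  c(stack, list(slab(jig$plate_material, jig$plate_bottom_cm)))
}
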