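#' Setup tolerances for the sensitivity analysis
#'
#' Thickness and density tolerances of the attenuating components in
#' front of the cell layer. Defaults reflect the fabrication and
#' vendor specifications of the setup: jig steps milled to +/- 3 um,
#' film thickness to +/- 1%, plate bottoms moulded to +/- 50 um, and
#' material densities known to +/- 0.5%. These are reconstructed
#' working values, intended to be overridden from the configuration
#' when better component data are available.
#'
#' @param step_cm Jig-step thickness tolerance, cm.
#' @param film_frac Film thickness tolerance as a fraction.
#' @param plate_bottom_cm Plate-bottom thickness tolerance, cm.
#' @param density_frac Density tolerance as a fraction (applied to the
#'   water-equivalent ratio, to which WET is proportional).
#' @return An object of class `setup_tolerances`.
#' @export
setup_tolerances <- function(step_cm = 3e-4, film_frac = 0.01,
                             plate_bottom_cm = 5e-3, density_frac = 0.005) {
  tol <- c(step_cm, film_frac, plate_bottom_cm, density_frac)
  if (any(!is.finite(tol)) || any(tol < 0)) stop("tolerances must be >= 0")
  structure(list(step_cm = step_cm, film_frac = film_frac,
                 plate_bottom_cm = plate_bottom_cm,
                 density_frac = density_frac),
            class = "setup_tolerances")
}

#' Low / nominal / high setups from coherent tolerance stacking
#'
#' Applies every tolerance coherently toward a shorter (low) or longer
#' (high) water-equivalent stack: thicknesses shifted by their
#' tolerance and water-equivalent ratios scaled by the density
#' tolerance, all with the same sign. This worst-case stacking brackets
#' the nominal geometry.
#'
#' @param jig Nominal [jig_geometry()].
#' @param tol A [setup_tolerances()].
#' @return A named list of three `jig_geometry` objects: `low`,
#'   `nominal`, `high`.
#' @export
perturb_setup <- function(jig, tol = setup_tolerances()) {
  stopifnot(inherits(jig, "jig_geometry"), inherits(tol, "setup_tolerances"))
  shift <- function(sign) {
    j <- jig
    j$step_thickness_cm <- pmax(0, j$step_thickness_cm + sign * tol$step_cm)
    j$film_thickness_um <- j$film_thickness_um * (1 + sign * tol$film_frac)
    j$plate_bottom_cm <- max(0, j$plate_bottom_cm + sign * tol$plate_bottom_cm)
    for (m in c("step_material", "film_material", "plate_material")) {
      j[[m]]$wer <- j[[m]]$wer * (1 + sign * tol$density_frac)
    }
    j
  }
  list(low = shift(-1), nominal = jig, high = shift(+1))
}

#' Propagate setup tolerances to per-column dose and LET uncertainty
#'
#' Evaluates the column conditions under the low, nominal and high
#' setups; the uncertainty assigned to each column is the mean absolute
#' deviation of the low and high evaluations from the nominal, for
#' both relative dose and dose-averaged LET. Uncertainties are largest
#' where the dose gradient is steep, i.e. in the distal-falloff
#' columns.
#'
#' @param beam A [beam_spec()].
#' @param setups A list as returned by [perturb_setup()], or a nominal
#'   [jig_geometry()] (perturbed with default tolerances).
#' @param tol Tolerances used when `setups` is a bare geometry.
#' @return The nominal [column_conditions()] data frame with extra
#'   columns `dose_rel_unc`, `dose_cGy_per_painting_unc` and
#'   `let_d_unc_keV_um`.
#' @export
propagate_uncertainty <- function(beam, setups, tol = setup_tolerances()) {
  if (inherits(setups, "jig_geometry")) setups <- perturb_setup(setups, tol)
  stopifnot(all(c("low", "nominal", "high") %in% names(setups)))
  cc <- lapply(setups[c("low", "nominal", "high")],
               function(j) column_conditions(beam, j))
  nom <- cc$nominal
  band <- function(field) {
    lo <- abs(cc$low[[field]] - nom[[field]])
    hi <- abs(cc$high[[field]] - nom[[field]])
    (lo + hi) / 2
  }
  nom$dose_rel_unc <- band("dose_rel")
  nom$dose_cGy_per_painting_unc <- band("dose_cGy_per_painting")
  let_lo <- abs(cc$low$let_d_keV_um - nom$let_d_keV_um)
  let_hi <- abs(cc$high$let_d_keV_um - nom$let_d_keV_um)
  nom$let_d_unc_keV_um <- (let_lo + let_hi) / 2
  nom
}
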