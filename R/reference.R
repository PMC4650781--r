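#' Published linear-quadratic parameters for the mapped cell lines
#'
#' Weighted linear-quadratic fit parameters reported for the H460 and
#' H1437 non-small-cell lung cancer lines irradiated across a scanned
#' proton Bragg curve at twelve dose-averaged LET values, together
#' with the 137Cs photon reference for each line and the reported RBE
#' at 10% surviving fraction. These values serve as defaults for the
#' synthetic-data generator and as inputs to the deterministic
#' round-trip analyses (SF2, D10, RBE reproduction).
#'
#' @param cell_line `"H460"` or `"H1437"`.
#' @return A data frame with columns `cell_line`, `radiation`
#'   (`"proton"`/`"photon"`), `let_keV_um` (NA for photons),
#'   `alpha` (1/Gy), `beta` (1/Gy^2) and `rbe_reported`.
#' @export
reference_lq_params <- function(cell_line = c("H460", "H1437")) {
  cell_line <- match.arg(cell_line)
  let <- c(0.9, 1.2, 1.6, 1.8, 1.9, 2.3, 3.0, 5.1, 10.8, 15.2, 17.7, 19.0)
  if (cell_line == "H460") {
    alpha <- c(0.268, 0.226, 0.151, 0.150, 0.166, 0.137,
               0.206, 0.117, 0.318, 0.446, 0.596, 0.883)
    beta <- c(0.097, 0.112, 0.134, 0.134, 0.134, 0.146,
              0.125, 0.159, 0.154, 0.341, 0.662, 0.956)
    rbe <- c(1.03, 1.04, 1.05, 1.05, 1.06, 1.07,
             1.07, 1.10, 1.28, 1.87, 2.58, 3.28)
    photon <- c(alpha = 0.290, beta = 0.083)
  } else {
    alpha <- c(0.077, 0.136, 0.067, 0.059, 0.094, 0.096,
               0.111, 0.034, 0.119, 0.180, 0.328, 0.360)
    beta <- c(0.028, 0.020, 0.027, 0.038, 0.031, 0.032,
              0.033, 0.052, 0.054, 0.095, 0.149, 0.272)
    rbe <- c(0.89, 0.88, 0.85, 0.98, 0.96, 0.97,
             1.02, 1.10, 1.26, 1.70, 2.33, 2.98)
    photon <- c(alpha = 0.050, beta = 0.041)
  }
  rbind(
    data.frame(cell_line = cell_line, radiation = "proton",
               let_keV_um = let, alpha = alpha, beta = beta,
               rbe_reported = rbe),
    data.frame(cell_line = cell_line, radiation = "photon",
               let_keV_um = NA_real_, alpha = photon[["alpha"]],
               beta = photon[["beta"]], rbe_reported = 1.00)
  )
}

#' Published photon reference fit as an `lq_fit`
#'
#' @param cell_line `"H460"` or `"H1437"`.
#' @return An [lq_fit()] built from the published 137Cs photon
#'   parameters (standard errors were not published and are set to 0).
#' @export
reference_photon_fit <- function(cell_line = c("H460", "H1437")) {
  cell_line <- match.arg(cell_line)
  p <- reference_lq_params(cell_line)
  ph <- p[p$radiation == "photon", ]
  lq_fit(ph$alpha, ph$beta, label = paste0(cell_line, " photons (137Cs)"))
}

#' Published proton fits as a named list of `lq_fit` objects
#'
#' @param cell_line `"H460"` or `"H1437"`.
#' @return A named list of [lq_fit()]; names are the LET values in
#'   keV/um.
#' @export
reference_proton_fits <- function(cell_line = c("H460", "H1437")) {
  cell_line <- match.arg(cell_line)
  p <- reference_lq_params(cell_line)
  pr <- p[p$radiation == "proton", ]
  fits <- lapply(seq_len(nrow(pr)), function(i) {
    lq_fit(pr$alpha[i], pr$beta[i],
           label = sprintf("%s %.1f keV/um", cell_line, pr$let_keV_um[i]))
  })
  names(fits) <- pr$let_keV_um
  fits
}
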