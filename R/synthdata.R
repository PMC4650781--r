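# run expr under a local RNG state so generators are reproducible
# without disturbing the caller's stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Design of a synthetic clonogenic mapping experiment
#'
#' Collects everything the plate generator needs: the per-column
#' linear-quadratic parameters (defaults to the published fits for the
#' chosen cell line, assigned to columns in order of increasing LET),
#' the photon reference parameters, seeding density, plating
#' efficiency, the entrance (column 1) dose levels, and the number of
#' plates per dose level (two plates of 8 wells per column give 16
#' replicate wells per dose-LET combination).
#'
#' Plating efficiencies were not published; the defaults (0.8 for
#' H460, 0.5 for H1437) are explicit configuration, not claims. The
#' default entrance dose levels 0, 0.5, 1, 2, 4, 6 Gy stand in for the
#' unpublished delivered levels.
#'
#' @param cell_line `"H460"` or `"H1437"`.
#' @param lq_params Data frame with columns `let_keV_um`, `alpha`,
#'   `beta` for the 12 columns (default: published proton fits).
#' @param photon_params Numeric `c(alpha, beta)` for the photon
#'   reference.
#' @param seeded_per_well Cells seeded per well.
#' @param plating_efficiency Fraction of unirradiated cells forming
#'   colonies.
#' @param dose_levels_Gy Entrance dose levels (column 1), Gy.
#' @param plates_per_dose Plates irradiated per dose level.
#' @param seed Integer seed recorded with the design.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(cell_line = c("H460", "H1437"),
                              lq_params = NULL, photon_params = NULL,
                              seeded_per_well = 100,
                              plating_efficiency = NULL,
                              dose_levels_Gy = c(0, 0.5, 1, 2, 4, 6),
                              plates_per_dose = 2,
                              seed = 1L) {
  cell_line <- match.arg(cell_line)
  ref <- reference_lq_params(cell_line)
  if (is.null(lq_params)) {
    lq_params <- ref[ref$radiation == "proton", c("let_keV_um", "alpha", "beta")]
  }
  if (is.null(photon_params)) {
    ph <- ref[ref$radiation == "photon", ]
    photon_params <- c(alpha = ph$alpha, beta = ph$beta)
  }
  if (is.null(plating_efficiency)) {
    plating_efficiency <- if (cell_line == "H460") 0.8 else 0.5
  }
  if (plating_efficiency <= 0 || plating_efficiency > 1) {
    stop("plating efficiency must be in (0, 1]")
  }
  if (plates_per_dose < 1) stop("plates_per_dose must be >= 1")
  structure(list(cell_line = cell_line, lq_params = lq_params,
                 photon_params = photon_params,
                 seeded_per_well = seeded_per_well,
                 plating_efficiency = plating_efficiency,
                 dose_levels_Gy = dose_levels_Gy,
                 plates_per_dose = as.integer(plates_per_dose),
                 seed = as.integer(seed)),
            class = "experiment_design")
}

#' Simulate one 96-well plate of colony counts
#'
#' Each well's colony count is Poisson with mean
#' seeded * PE * exp(-alpha_c D_c - beta_c D_c^2), where D_c is the
#' column's absolute dose (paintings times the column's dose per
#' painting) and (alpha_c, beta_c) the column's LQ parameters from the
#' design, assigned to columns in order. Zero paintings yields a
#' control plate with counts around seeded * PE. An optional
#' log-normal multiplier on the plate's effective seeding density
#' emulates the 15-30% counting error of a stock cell solution
#' (disabled by default; the analysis itself assumes Poisson wells).
#'
#' @param design An [experiment_design()].
#' @param conditions A [column_conditions()] data frame.
#' @param paintings Integer number of repaintings (>= 0).
#' @param seed Optional seed for this plate (default: draw from the
#'   current RNG stream).
#' @param seeding_cv Coefficient of variation of the optional
#'   log-normal plate-level seeding multiplier (0 = off).
#' @param plate_id,replicate_id Identifiers.
#' @return A [plate_counts()] object whose condition map records the
#'   per-column absolute dose and LET.
#' @export
simulate_plate <- function(design, conditions, paintings, seed = NULL,
                           seeding_cv = 0, plate_id = NULL, replicate_id = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  if (paintings < 0) stop("paintings must be >= 0")
  lq <- design$lq_params
  if (nrow(lq) != 12L) stop("design must carry 12 per-column parameter sets")
  dose_Gy <- paintings * conditions$dose_cGy_per_painting / 100
  dose_Gy[conditions$beyond_range] <- 0
  .with_seed(seed, {
    seeding <- design$seeded_per_well
    if (seeding_cv > 0) {
      sdlog <- sqrt(log(1 + seeding_cv^2))
      seeding <- seeding * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
    }
    sf <- exp(-lq$alpha * dose_Gy - lq$beta * dose_Gy^2)
    mu <- seeding * design$plating_efficiency * sf
    counts <- matrix(stats::rpois(96, rep(mu, each = 8)), nrow = 8)
    plate_counts(
      counts, seeded_per_well = design$seeded_per_well,
      conditions = data.frame(column = 1:12, dose_Gy = dose_Gy,
                              let_keV_um = conditions$let_d_keV_um),
      plate_id = if (is.null(plate_id))
        sprintf("%s_p%d_r%d", design$cell_line, paintings, replicate_id)
      else plate_id,
      replicate_id = replicate_id
    )
  })
}

#' Simulate a single-condition survival experiment
#'
#' Poisson colony counts for one (alpha, beta) condition at a set of
#' doses, `wells_per_dose` replicate wells each - the building block of
#' the parameter-recovery studies. Returns pooled survival points ready
#' for [fit_lq()].
#'
#' @param alpha,beta LQ parameters of the simulated truth.
#' @param doses_Gy Dose levels, Gy.
#' @param wells_per_dose Replicate wells per dose level.
#' @param seeded_per_well Cells seeded per well.
#' @param pe Plating efficiency.
#' @param seed Optional seed.
#' @return A survival-point data frame (as from
#'   [survival_fractions()]).
#' @export
simulate_survival_experiment <- function(alpha, beta, doses_Gy,
                                         wells_per_dose = 16,
                                         seeded_per_well = 100, pe = 0.8,
                                         seed = NULL) {
  .with_seed(seed, {
    denom <- seeded_per_well * pe
    rows <- lapply(seq_along(doses_Gy), function(i) {
      d <- doses_Gy[i]
      mu <- denom * exp(-alpha * d - beta * d^2)
      wells <- stats::rpois(wells_per_dose, mu)
      data.frame(column = i, dose_Gy = d, let_keV_um = NA_real_,
                 sf = mean(wells) / denom,
                 sem = stats::sd(wells) / sqrt(wells_per_dose) / denom,
                 n_wells = wells_per_dose, cells_eff = denom)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("survival_points", "data.frame")
    out
  })
}

#' Dose levels spanning a survival curve down to the detection limit
#'
#' Evenly spaced dose levels from 0 to the dose at which the expected
#' SF reaches twice the limit of detection - the widest range a
#' clonogenic screen at this seeding density can measure for the given
#' radiosensitivity. Used by the recovery studies; mirrors how
#' achievable doses are cell-line dependent in practice.
#'
#' @param alpha,beta LQ parameters.
#' @param n_levels Number of dose levels (including 0).
#' @param seeded_per_well,pe Seeding density and plating efficiency
#'   setting the LOD.
#' @return Numeric vector of doses in Gy.
#' @export
recovery_doses <- function(alpha, beta, n_levels = 6,
                           seeded_per_well = 100, pe = 0.8) {
  sf_min <- min(0.9, 2 * lod_threshold(seeded_per_well, pe))
  dmax <- dose_at_sf(lq_fit(alpha, beta), sf_min)
  seq(0, dmax, length.out = n_levels)
}

#' Simulate a track-step event stream with a prescribed LET spectrum
#'
#' Generates (energy deposition, step length) pairs whose event LET
#' epsilon/l follows the requested distribution. Every step deposits
#' the same energy, so the sampled epsilon/l values are themselves the
#' dose-weighted spectrum (each step carries equal dose weight) and
#' the expected dose-averaged LET equals the distribution mean, while
#' the track average is the harmonic mean - strictly lower whenever the
#' spectrum has spread.
#'
#' Supported spectra: `delta` (constant `value`), `uniform`
#' (`min`, `max`), `lognormal` (`meanlog`, `sdlog`), and `mixture`
#' (two truncated log-normal components: `weights`, `meanlog`,
#' `sdlog`, `range`), the last emulating the wide distal-column
#' mixtures where slowed primaries span tens of keV/um.
#'
#' @param spec A list with elements `type`, `n`, and the parameters of
#'   the chosen type; see [distal_mixture_spec()] for a ready-made
#'   distal spectrum.
#' @param seed Optional seed.
#' @param epsilon_keV Energy deposited per step, keV.
#' @return A [track_steps()] stream of `spec$n` events.
#' @export
simulate_tracks <- function(spec, seed = NULL, epsilon_keV = 1) {
  if (!is.list(spec) || is.null(spec$type) || is.null(spec$n)) {
    stop("spec must be a list with elements 'type' and 'n'")
  }
  n <- spec$n
  if (n < 1) stop("spec$n must be >= 1")
  L <- .with_seed(seed, switch(
    spec$type,
    delta = {
      if (is.null(spec$value) || spec$value <= 0) stop("delta spec needs value > 0")
      rep(spec$value, n)
    },
    uniform = {
      if (is.null(spec$min) || is.null(spec$max) || spec$min <= 0 ||
          spec$max <= spec$min) stop("uniform spec needs 0 < min < max")
      stats::runif(n, spec$min, spec$max)
    },
    lognormal = {
      if (is.null(spec$meanlog) || is.null(spec$sdlog) || spec$sdlog < 0) {
        stop("lognormal spec needs meanlog and sdlog >= 0")
      }
      stats::rlnorm(n, spec$meanlog, spec$sdlog)
    },
    mixture = {
      w <- spec$weights
      if (is.null(w) || length(w) != length(spec$meanlog) ||
          any(w < 0) || sum(w) <= 0) stop("mixture spec needs matching positive weights")
      comp <- sample.int(length(w), n, replace = TRUE, prob = w)
      x <- stats::rlnorm(n, spec$meanlog[comp], spec$sdlog[comp])
      if (!is.null(spec$range)) {
        # resample out-of-range draws (truncation)
        bad <- x < spec$range[1] | x > spec$range[2]
        while (any(bad)) {
          comp2 <- sample.int(length(w), sum(bad), replace = TRUE, prob = w)
          x[bad] <- stats::rlnorm(sum(bad), spec$meanlog[comp2], spec$sdlog[comp2])
          bad <- x < spec$range[1] | x > spec$range[2]
        }
      }
      x
    },
    stop("unknown spectrum type: ", spec$type)
  ))
  track_steps(epsilon_keV = rep(epsilon_keV, n), length_um = epsilon_keV / L)
}

#' Distal-column LET spectrum specification
#'
#' A two-component truncated log-normal mixture supported on 3-80
#' keV/um whose dose-weighted mean is about 19 keV/um: the bulk of the
#' dose near 10 keV/um from protons just past the peak plus a slowed
#' tail around 55 keV/um. A synthetic stand-in for the wide epsilon/l
#' spread scored in the last plate column.
#'
#' @param n Number of events.
#' @return A spectrum spec for [simulate_tracks()].
#' @export
distal_mixture_spec <- function(n = 1e5) {
  list(type = "mixture", n = n, weights = c(0.8, 0.2),
       meanlog = log(c(10, 55)), sdlog = c(0.35, 0.25), range = c(3, 80))
}

#' Simulate per-nucleus DNA double-strand-break focus counts
#'
#' Focus counts per nucleus are Poisson with mean dose * yield, the
#' yield (foci per Gy) depending on LET. The default yield curve is
#' calibrated to reported means of 3.57 foci per nucleus at
#' 4.6 keV/um (2.9 Gy) and 7.02 at 17.3 keV/um (1.7 Gy), interpolated
#' linearly in LET; these anchors calibrate the generator and are not
#' model predictions.
#'
#' @param dose_Gy Delivered dose, Gy.
#' @param let_keV_um Dose-averaged LET used to look up the yield
#'   (ignored when `yield_per_Gy` is given).
#' @param yield_per_Gy Foci per nucleus per Gy; overrides the LET
#'   lookup.
#' @param n_nuclei Number of nuclei scored.
#' @param seed Optional seed.
#' @return Integer vector of per-nucleus focus counts.
#' @export
simulate_foci <- function(dose_Gy, let_keV_um = NULL, yield_per_Gy = NULL,
                          n_nuclei = 200, seed = NULL) {
  if (n_nuclei < 1) stop("n_nuclei must be >= 1")
  if (dose_Gy < 0) stop("dose must be >= 0")
  if (is.null(yield_per_Gy)) {
    if (is.null(let_keV_um)) stop("give either let_keV_um or yield_per_Gy")
    anchors_let <- c(4.6, 17.3)
    anchors_yield <- c(3.57 / 2.9, 7.02 / 1.7)
    slope <- diff(anchors_yield) / diff(anchors_let)
    yield_per_Gy <- max(0, anchors_yield[1] + slope * (let_keV_um - anchors_let[1]))
  }
  if (yield_per_Gy < 0) stop("yield must be >= 0")
  .with_seed(seed, stats::rpois(n_nuclei, dose_Gy * yield_per_Gy))
}
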