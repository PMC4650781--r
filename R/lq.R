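#' Linear-quadratic fit object
#'
#' Container for the parameters of the linear-quadratic survival model
#' SF(D) = exp(-alpha D - beta D^2), with standard errors and the
#' alpha-beta covariance. Construct directly from published parameters
#' or obtain from [fit_lq()].
#'
#' @param alpha Linear coefficient, 1/Gy.
#' @param beta Quadratic coefficient, 1/Gy^2.
#' @param se_alpha,se_beta Standard errors (>= 0).
#' @param cov_ab Covariance of the alpha and beta estimates.
#' @param rss Weighted residual sum of squares of the fit (if any).
#' @param dof Residual degrees of freedom.
#' @param label Optional label (e.g. cell line / LET).
#' @return An object of class `lq_fit`.
#' @export
lq_fit <- function(alpha, beta, se_alpha = 0, se_beta = 0, cov_ab = 0,
                   rss = NA_real_, dof = NA_integer_, label = NULL) {
  stopifnot(is.numeric(alpha), is.numeric(beta),
            se_alpha >= 0, se_beta >= 0)
  vcov <- matrix(c(se_alpha^2, cov_ab, cov_ab, se_beta^2), 2, 2,
                 dimnames = list(c("alpha", "beta"), c("alpha", "beta")))
  structure(list(alpha = alpha, beta = beta,
                 se_alpha = se_alpha, se_beta = se_beta,
                 vcov = vcov, rss = rss, dof = dof, label = label),
            class = "lq_fit")
}

#' @export
print.lq_fit <- function(x, ...) {
  cat(sprintf("<lq_fit>%s alpha = %.3f +/- %.3f /Gy, beta = %.3f +/- %.3f /Gy^2\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$alpha, x$se_alpha, x$beta, x$se_beta))
  if (is.finite(x$rss)) {
    cat(sprintf("  weighted RSS %.4g on %d dof\n", x$rss, x$dof))
  }
  invisible(x)
}

#' Surviving fraction predicted at a dose
#'
#' SF(D) = exp(-alpha D - beta D^2). SF(0) = 1 and SF is strictly
#' decreasing in dose for non-negative parameters.
#'
#' @param fit An [lq_fit()].
#' @param dose_Gy Dose in Gy (vectorised, >= 0).
#' @return Surviving fraction(s).
#' @export
sf_at_dose <- function(fit, dose_Gy) {
  stopifnot(inherits(fit, "lq_fit"))
  if (any(dose_Gy < 0)) stop("dose must be >= 0")
  exp(-fit$alpha * dose_Gy - fit$beta * dose_Gy^2)
}

#' Isoeffect dose for a target surviving fraction
#'
#' Solves exp(-alpha D - beta D^2) = sf for the positive root:
#' D = (-alpha + sqrt(alpha^2 - 4 beta ln sf)) / (2 beta), reducing to
#' D = -ln(sf)/alpha when beta = 0. Inverse of [sf_at_dose()].
#'
#' @param fit An [lq_fit()].
#' @param sf Target surviving fraction, strictly between 0 and 1.
#' @return Dose in Gy.
#' @export
dose_at_sf <- function(fit, sf) {
  stopifnot(inherits(fit, "lq_fit"))
  if (any(sf <= 0) || any(sf >= 1)) stop("surviving fraction must be in (0, 1)")
  a <- fit$alpha; b <- fit$beta
  if (a == 0 && b == 0) stop("alpha and beta cannot both be zero")
  ls <- log(sf)
  if (abs(b) < 1e-12) {
    d <- -ls / a
  } else {
    disc <- a^2 - 4 * b * ls
    if (any(disc < 0)) stop("no real isoeffect dose for these parameters")
    d <- (-a + sqrt(disc)) / (2 * b)
  }
  if (any(d <= 0)) stop("no positive isoeffect dose for these parameters")
  d
}

# gradient of the isoeffect dose w.r.t. (alpha, beta):
# from beta D^2 + alpha D + ln sf = 0,
#   dD/dalpha = -D / (alpha + 2 beta D), dD/dbeta = -D^2 / (alpha + 2 beta D)
.dose_grad <- function(fit, d) {
  denom <- fit$alpha + 2 * fit$beta * d
  c(-d / denom, -d^2 / denom)
}

#' Relative biological effectiveness at an isoeffect level
#'
#' RBE = D_reference / D_test, the ratio of the doses at which the
#' reference (photon) and test curves reach the same surviving
#' fraction. The standard deviation is obtained by propagating the
#' standard errors (and alpha-beta covariance) of both fits through the
#' isoeffect roots with the delta method, treating the two fits as
#' independent.
#'
#' @param reference Reference [lq_fit()] (photons).
#' @param test Test [lq_fit()] (e.g. one proton LET condition).
#' @param level Surviving fraction defining the isoeffect (default
#'   0.10).
#' @return An object of class `rbe_result`: list with `rbe`, `sd`,
#'   `level`, `dose_reference_Gy`, `dose_test_Gy`.
#' @export
rbe <- function(reference, test, level = 0.10) {
  stopifnot(inherits(reference, "lq_fit"), inherits(test, "lq_fit"))
  if (level <= 0 || level >= 1) stop("survival level must be in (0, 1)")
  d_ref <- dose_at_sf(reference, level)
  d_tst <- dose_at_sf(test, level)
  value <- d_ref / d_tst
  g_ref <- .dose_grad(reference, d_ref)
  g_tst <- .dose_grad(test, d_tst)
  var_ref <- drop(t(g_ref) %*% reference$vcov %*% g_ref)
  var_tst <- drop(t(g_tst) %*% test$vcov %*% g_tst)
  sd <- value * sqrt(var_ref / d_ref^2 + var_tst / d_tst^2)
  structure(list(rbe = value, sd = sd, level = level,
                 dose_reference_Gy = d_ref, dose_test_Gy = d_tst),
            class = "rbe_result")
}

#' @export
print.rbe_result <- function(x, ...) {
  cat(sprintf("<rbe_result> RBE at SF = %.2f: %.2f +/- %.2f (D_ref %.2f Gy / D_test %.2f Gy)\n",
              x$level, x$rbe, x$sd, x$dose_reference_Gy, x$dose_test_Gy))
  invisible(x)
}

#' Weighted linear-quadratic fit to survival data
#'
#' Fits SF(D) = exp(-alpha D - beta D^2) by weighted (1/Y) nonlinear
#' least squares: minimise sum w_i (SF_i - SF(D_i))^2 with
#' w_i = 1/SF_i using the observed fractions, floored at
#' `weight_floor` so a very small observation cannot dominate. The fit
#' is on the linear SF scale.
#'
#' Two covariance conventions are available. `"counting"` (the default
#' when the points carry well counts) uses the sampling variance
#' implied by Poisson colony counting, Var(SF_i) = SF_i / (n_wells_i *
#' cells_eff_i) with cells_eff the product of cells seeded and plating
#' efficiency: the covariance is then the inverse information matrix
#' with no residual-based dispersion factor, which stays calibrated
#' even with few dose levels. `"residual"` estimates the dispersion
#' from the weighted residuals (RSS/dof), the convention of common
#' curve-fitting software.
#'
#' @param points Data frame of survival points with columns `dose_Gy`
#'   and `sf`; optional `n_wells` and `cells_eff` enable the counting
#'   covariance (see [survival_fractions()]).
#' @param variance Covariance convention, `"counting"` or
#'   `"residual"`. Default picks `"counting"` when the columns are
#'   available.
#' @param weight_floor Floor applied to observed SF in the weights
#'   (default: the smallest positive observed SF).
#' @param nonneg Constrain alpha, beta >= 0 (default FALSE; published
#'   fits are unconstrained).
#' @return An [lq_fit()] with standard errors, covariance, weighted
#'   RSS and degrees of freedom; the fitted points are attached as
#'   attribute `"points"`.
#' @export
fit_lq <- function(points, variance = NULL, weight_floor = NULL,
                   nonneg = FALSE) {
  if (!is.data.frame(points) || !all(c("dose_Gy", "sf") %in% names(points))) {
    stop("points must be a data frame with columns 'dose_Gy' and 'sf'")
  }
  pts <- points[is.finite(points$dose_Gy) & is.finite(points$sf), , drop = FALSE]
  if (length(unique(pts$dose_Gy)) < 3L) {
    stop("insufficient data: need at least 3 distinct dose levels")
  }
  has_counting <- all(c("n_wells", "cells_eff") %in% names(pts)) &&
    all(is.finite(pts$n_wells)) && all(is.finite(pts$cells_eff))
  if (is.null(variance)) variance <- if (has_counting) "counting" else "residual"
  variance <- match.arg(variance, c("counting", "residual"))
  if (variance == "counting" && !has_counting) {
    stop("counting covariance needs 'n_wells' and 'cells_eff' columns")
  }
  if (is.null(weight_floor)) {
    pos <- pts$sf[pts$sf > 0]
    if (length(pos) == 0L) stop("all survival fractions are zero")
    weight_floor <- min(pos)
  }
  sf_w <- pmax(pts$sf, weight_floor)
  w <- 1 / sf_w
  # log-linear start: -log SF ~ alpha D + beta D^2
  start_fit <- stats::lm(-log(sf_w) ~ 0 + dose_Gy + I(dose_Gy^2), data = pts)
  start <- stats::coef(start_fit)
  start[!is.finite(start)] <- 0
  if (nonneg) start <- pmax(start, 0)
  sw <- sqrt(w)
  model <- function(p) exp(-p[1] * pts$dose_Gy - p[2] * pts$dose_Gy^2)
  fit <- minpack.lm::nls.lm(
    par = c(start[[1]], start[[2]]),
    lower = if (nonneg) c(0, 0) else c(-Inf, -Inf),
    fn = function(p) sw * (pts$sf - model(p)),
    jac = function(p) {
      mu <- model(p)
      cbind(sw * pts$dose_Gy * mu, sw * pts$dose_Gy^2 * mu)
    },
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (fit$info %in% c(0, 9) || any(!is.finite(fit$par))) {
    stop("linear-quadratic fit failed to converge: ", fit$message)
  }
  a <- fit$par[1]; b <- fit$par[2]
  mu <- exp(-a * pts$dose_Gy - b * pts$dose_Gy^2)
  resid <- pts$sf - mu
  rss <- sum(w * resid^2)
  dof <- nrow(pts) - 2L
  J <- cbind(alpha = -pts$dose_Gy * mu, beta = -pts$dose_Gy^2 * mu)
  if (variance == "counting") {
    v <- sf_w / (pts$n_wells * pts$cells_eff)
    info <- t(J) %*% (J / v)
    vc <- solve(info)
  } else {
    if (dof < 1L) stop("insufficient data: no residual degrees of freedom")
    sigma2 <- rss / dof
    vc <- sigma2 * solve(t(J) %*% (J * w))
  }
  out <- lq_fit(a, b, se_alpha = sqrt(vc[1, 1]), se_beta = sqrt(vc[2, 2]),
                cov_ab = vc[1, 2], rss = rss, dof = dof)
  attr(out, "points") <- pts
  attr(out, "weight_floor") <- weight_floor
  out
}

#' Extra sum-of-squares F test between two survival curves
#'
#' Compares the fit of separate linear-quadratic curves to the two
#' datasets against a single pooled curve. The statistic is
#' F = ((RSS_pooled - RSS_separate)/2) / (RSS_separate / dof_separate)
#' with weighted residual sums of squares, 2 extra parameters, and
#' dof_separate = n_A + n_B - 4; the p-value is the upper tail of the
#' F(2, dof) distribution. Identical datasets give F = 0, p = 1.
#'
#' @param points_a,points_b Survival-point data frames as for
#'   [fit_lq()].
#' @param ... Passed to [fit_lq()].
#' @return A list with `f`, `p_value`, `fit_a`, `fit_b`, `fit_pooled`.
#' @export
compare_lq_ftest <- function(points_a, points_b, ...) {
  floor_ab <- min(c(points_a$sf[points_a$sf > 0], points_b$sf[points_b$sf > 0]))
  fa <- fit_lq(points_a, weight_floor = floor_ab, ...)
  fb <- fit_lq(points_b, weight_floor = floor_ab, ...)
  pooled <- rbind(points_a[c("dose_Gy", "sf")], points_b[c("dose_Gy", "sf")])
  fp <- fit_lq(pooled, variance = "residual", weight_floor = floor_ab, ...)
  rss_sep <- fa$rss + fb$rss
  dof_sep <- fa$dof + fb$dof
  f <- max(0, ((fp$rss - rss_sep) / 2) / (rss_sep / dof_sep))
  p <- stats::pf(f, 2, dof_sep, lower.tail = FALSE)
  list(f = f, p_value = p, fit_a = fa, fit_b = fb, fit_pooled = fp)
}

#' Summary table of LQ parameters, SF2, D10 and RBE across LET
#'
#' Builds the standard reporting table for a set of fits at different
#' dose-averaged LET values against a common photon reference: one row
#' per LET with alpha, beta, their standard errors, the surviving
#' fraction at 2 Gy, the 10%-survival dose and the RBE with its
#' propagated standard deviation. Rows whose isoeffect dose is
#' undefined (e.g. both parameters non-positive) are retained with NA
#' in the affected cells.
#'
#' @param fits Named list of [lq_fit()] objects; names are the LET
#'   values in keV/um.
#' @param reference Photon reference [lq_fit()].
#' @param level Isoeffect survival level (default 0.10).
#' @param sf_dose Dose at which to report SF (default 2 Gy).
#' @return A data frame with columns `let_keV_um`, `alpha`, `beta`,
#'   `se_alpha`, `se_beta`, `sf2`, `d10_Gy`, `rbe`, `rbe_sd`.
#' @export
rbe_let_table <- function(fits, reference, level = 0.10, sf_dose = 2) {
  stopifnot(length(fits) >= 1L, inherits(reference, "lq_fit"))
  if (is.null(names(fits))) stop("fits must be a named list (names = LET values)")
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    stopifnot(inherits(f, "lq_fit"))
    d10 <- tryCatch(dose_at_sf(f, level), error = function(e) NA_real_)
    r <- if (is.finite(d10)) rbe(reference, f, level) else NULL
    data.frame(
      let_keV_um = as.numeric(nm),
      alpha = f$alpha, beta = f$beta,
      se_alpha = f$se_alpha, se_beta = f$se_beta,
      sf2 = sf_at_dose(f, sf_dose),
      d10_Gy = d10,
      rbe = if (is.null(r)) NA_real_ else r$rbe,
      rbe_sd = if (is.null(r)) NA_real_ else r$sd
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
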