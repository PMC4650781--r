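---
title: "Mapping dose, LET and RBE along a scanned proton Bragg curve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping dose, LET and RBE along a scanned proton Bragg curve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braggmap)
```

## The experimental idea

The biologic effectiveness of a proton beam rises toward the end of its
range because the linear energy transfer (LET) of the slowing protons
rises. A clean way to measure this is to irradiate a 96-well plate
through a 12-step Lucite range shifter ("jig"): each plate column sits
behind a different step thickness and therefore samples a different
point on the pristine Bragg curve — a different (dose, dose-averaged
LET) pair — in a single exposure. Clonogenic survival per column,
normalised to a photon reference, then maps relative biological
effectiveness (RBE) against LET with 12 conditions per plate.

`braggmap` implements each stage of this design as testable code: a
one-dimensional analytic transport model predicting the per-column dose
and LET, an event-level dose-averaged LET scorer, the clonogenic
survival analysis (weighted linear-quadratic fits, SF2, D10, RBE with
propagated uncertainty, extra sum-of-squares F tests), a
setup-tolerance sensitivity analysis, and generators that synthesise
every input the analysis consumes.

## Transport model

Proton range is modelled with the Bragg-Kleeman power law
$R = a E^p$ (water: $a = 0.0022$ cm/MeV$^p$, $p = 1.77$), and
stopping power as its derivative $S(E) = E^{1-p}/(a p)$. Other
materials enter through their water-equivalent ratio (WER): Lucite's
WER is fixed by the delivered beam's quoted ranges, 4.8 cm water
against 4.1 cm Lucite, making the water-to-Lucite range conversion
exact by construction. Films are treated as Lucite-equivalent slabs of
their printed 268 µm thickness; the polystyrene plate bottom's WER is
scaled from Lucite by the density ratio 1.09/1.19, since its
composition is not specified. Water-equivalent thickness (WET) is
additive over a stack of slabs.

The beam at the jig surface is described by a Gaussian residual-range
distribution. Its mean is the range of the *effective* energy — the
energy whose Bragg-Kleeman range equals the calibrated 4.8 cm, i.e.
76.97 MeV rather than the nominal 79.7 MeV, absorbing upstream nozzle
material we do not model. Its width combines the configured energy
spread (mapped through $dR/dE$) with range straggling (default 1.2% of
range) in quadrature. At depth $z$ the dose is the mean stopping power
of the surviving spectrum and the dose-averaged LET its dose-weighted
mean:

$$
D(z) \propto \int_z^\infty S(R-z)\,\varphi(R)\,dR, \qquad
\mathrm{LET}_d(z) = \frac{\int_z^\infty S(R-z)^2\,\varphi(R)\,dR}
                        {\int_z^\infty S(R-z)\,\varphi(R)\,dR}.
$$

The $u^{(1-p)/p}$ singularity of $S$ at zero residual range is removed
exactly by the substitutions $u = t^p$ (first moment) and
$u = s^{p/(2-p)}$ (second moment), after which a midpoint rule
converges quickly; node counts scale with $R_0/\sigma$ so narrow
spectra stay resolved. This model deliberately omits nuclear
interactions, secondary particles and lateral scattering: it is a
surrogate for the condensed-history Monte Carlo a treatment-planning
study would use, adequate for placing columns on the Bragg curve and
for exercising the downstream statistics.

### Calibrated, not predicted

Two beam parameters are calibrations, stated as such:

* **Effective energy** is solved from the printed 4.8 cm range.
* **Energy spread** (default 0.545 MeV) is chosen so that the modelled
  peak-to-entrance column dose ratio is 5.5, the value reported for the
  delivered configuration. The momentum spread of the real beamline was
  not published, so this ratio is reproduced, not predicted.

With these, the total range spread is ≈0.83 mm. A consequence worth
knowing: the model's dose-averaged LET at the Bragg-peak depth is
≈13.9 keV/µm, higher than the ≈10.8 keV/µm a full Monte Carlo assigns
to the peak column. A single spread parameter cannot match both the
5.5 dose ratio and the peak LET; we prioritise the dose ratio, and the
default geometry keeps column LET strictly monotone, which is what the
downstream analysis relies on.

## Default jig geometry

Exact step thicknesses were never published, only the design criteria:
12 steps, large increments in the plateau and increasingly fine ones
near the end of range, the Bragg peak aligned with column 9 after
inserting three 268 µm films. `default_jig()` therefore
reverse-engineers the geometry from the published per-column LET
values: column 1 has no step, columns 2–8 are placed where the model's
LET$_d$ reaches 1.2–5.1 keV/µm, column 9 at the dose-peak depth, and
columns 10–12 at 15.2, 17.7 and 19.0 keV/µm on the distal falloff.
LET$_d(z)$ is strictly increasing in this model, so the inversion is
unique. The plate-bottom thickness (1 mm) is a working default, set in
the packaged configuration.

```{r}
beam <- beam_spec()
cc <- column_conditions(beam, default_jig(beam))
round(cc[, c("column", "step_cm", "dose_rel", "let_d_keV_um")], 3)
```

## Event-level LET scoring

Monte Carlo track structure is summarised by steps of energy deposition
$\varepsilon$ over length $l$; $\varepsilon/l$ is treated as a random
variable form of LET. `score_let()` computes the track average
$\sum\varepsilon/\sum l$ and the dose average
$\sum \varepsilon(\varepsilon/l)/\sum\varepsilon$, plus the
dose-weighted $\varepsilon/l$ histogram (100 log-spaced bins).
LET$_d \ge$ LET$_t$ always, strictly when the spectrum has spread —
this Cauchy-Schwarz property is property-tested. Statistical
uncertainty uses batch means (default 10 contiguous batches), since the
estimator used originally was unspecified. Zero-$\varepsilon$ steps
keep their path length in the track average but carry no dose weight.

`simulate_tracks()` generates streams with a prescribed $\varepsilon/l$
law. Each step deposits equal energy, so the sampled values are
themselves the dose-weighted spectrum: the expected LET$_d$ is the
distribution mean and LET$_t$ the harmonic mean. The packaged
distal-column spectrum is a two-component truncated log-normal mixture
on 3–80 keV/µm (bulk near 10, tail near 55 keV/µm) calibrated so its
dose-weighted mean is ≈19 keV/µm, emulating the wide mixture scored in
the last plate column.

## Survival analysis

Colony counts (colonies of ≥50 cells, 100 cells seeded per well) are
normalised by the plating efficiency estimated from unirradiated
controls; per condition the 16 replicate wells (8 wells × 2 plates) are
pooled: SF = mean(counts)/(seeded × PE), with the SEM across wells.
Dose levels whose aggregate SF falls *strictly below* the limit of
detection 1/(seeded × PE) are dropped; a point exactly at the limit is
kept.

`fit_lq()` fits $SF(D) = e^{-\alpha D - \beta D^2}$ by weighted
nonlinear least squares with $1/Y$ weights on the observed fractions
(floored at the smallest positive observation so a near-zero point
cannot acquire infinite weight), on the linear SF scale, via
Levenberg-Marquardt with an analytic Jacobian. Parameters are
unconstrained by default (`nonneg = TRUE` is available); the published
fits are all positive, so the default suffices to reproduce them.

### Why the covariance uses counting statistics by default

With $k$ dose levels the residual degrees of freedom are $k-2$; a
dispersion factor estimated from 3–4 residuals is so noisy that
"within 2 SE" intervals undercover (the $t_{4}$ problem). But the
sampling variance of a pooled SF is known here a priori:
Var(SF) = SF/(n\_wells × seeded × PE) for Poisson wells. The default
covariance is therefore the inverse information matrix with this known
dispersion (`variance = "counting"`), which keeps the reported SEs
calibrated — the parameter-recovery study in the test suite verifies
≥90% two-SE coverage across all published parameter sets. The
residual-dispersion convention of common curve-fitting software is
available as `variance = "residual"` and is used wherever counting
metadata are absent (e.g. pooled fits in the F test).

Isoeffect doses come from the positive quadratic root of
$\beta D^2 + \alpha D + \ln s = 0$ (linear case handled separately),
RBE is the photon/test isoeffect-dose ratio, and its standard deviation
propagates both fits' standard errors and $\alpha$–$\beta$ covariances
through the root by the delta method, treating the two fits as
independent. Curves are compared with the extra sum-of-squares F test
(pooled single-curve fit versus separate fits, weighted residual sums
of squares, $F(2, n_A+n_B-4)$). No multiplicity correction is applied
by default — the original correction formula was not specified.

## Synthetic experiments and what they do (not) show

`simulate_plate()` draws each well's colony count as
Poisson(seeded × PE × SF(D\_column)), with the 12 published
($\alpha, \beta$) pairs assigned to columns in LET order, absolute
column doses from the painting calibration (2.6 cGy × dose\_rel per
painting, 17.64 MU each), and an optional log-normal plate-level
seeding multiplier emulating the 15–30% counting error of a stock cell
suspension (off by default — the analysis assumes Poisson wells).
Plating efficiencies were not published; defaults are 0.8 (H460) and
0.5 (H1437), explicit configuration rather than claims. Default
entrance dose levels {0, 0.5, 1, 2, 4, 6} Gy likewise stand in for
unpublished values. With 100 cells per well those entrance levels
cannot measure the distal high-LET columns (their SF falls below the
detection limit after the first level or two), so the per-condition
recovery studies use `recovery_doses()`: six levels evenly spanning 0
to the dose where the expected SF reaches twice the detection limit,
mirroring how achievable doses are cell-line dependent in a real
screen.

The generators reproduce the statistical structure the analysis
assumes — Poisson counting, replicate pooling, LOD censoring — not the
biology it abstracts: no cell-cycle effects, no bystander signalling,
no plating-density artefacts, no colony-segmentation error. Passing
recovery tests therefore validate the estimator chain, not the
biological model.

Problem sizes used by the shipped studies: 200 replicate experiments
per published parameter set (26 sets) for coverage calibration, 1000
replicate pairs for the F-test null size, 16 wells per dose level, and
2×10⁵-step streams for LET spectra. All generators take explicit
seeds and are reproducible stream-for-stream.

## Sensitivity analysis

The attenuating components in front of the cells (steps, films, plate
bottom) and the material densities carry tolerances: defaults are
±3 µm on steps (milling accuracy), ±1% film thickness, ±50 µm plate
bottom, ±0.5% densities — reconstructed working values, replaceable in
configuration. `perturb_setup()` stacks all tolerances coherently
toward shorter (low) or longer (high) water-equivalent paths;
`propagate_uncertainty()` evaluates the column conditions for the
three setups and assigns each column the mean absolute deviation of
low and high from nominal as its dose and LET uncertainty. Error bars
are largest in the distal-falloff columns, where the dose gradient is
steep; the entrance column's relative dose is pinned to 1 by the
normalisation. A random-sampling tolerance mode is intentionally out of
scope — the three deterministic setups are the published procedure.

## Numerical choices and degenerate inputs

* Depth grids: 100 µm steps, refined to 10 µm within 0.5 cm of the
  peak — resolves the 5 µm scoring layer's gradient without waste.
* Columns beyond the beam range are flagged `beyond_range` with zero
  dose, not an error; normalisation fails only if column 1 itself is
  beyond range.
* `dose_at_sf()` rejects levels outside (0, 1) and parameter pairs
  with no positive root; `rbe_let_table()` keeps such rows with NA
  cells rather than dropping them.
* Degenerate LET streams (constant $\varepsilon/l$) produce a single
  full-weight histogram bin and zero batch uncertainty; empty or
  all-zero-$\varepsilon$ streams raise a no-signal error.
* Identical datasets in the F test give F = 0, p = 1 — a defined
  result, not an error.
* Tie-break at the detection limit: "lower than the limit" is read as
  strict, so boundary points are retained.

## Limitations

* One spread parameter cannot reproduce both the 5.5 column dose ratio
  and the published peak-column LET; the geometry is calibrated to the
  former.
* The transport model has no nuclear interactions or secondaries, so
  absolute entrance LET (≈0.92 keV/µm here) and the distal LET scale
  agree with full Monte Carlo only at the 10–20% level.
* Published standard errors for the reference fits were not available;
  the reference `lq_fit` objects carry zero SEs, so round-trip RBE
  uncertainties from them are zero by construction.
* The 96-well format itself caps measurable SF at the detection limit
  1/(seeded × PE); high-dose, high-LET conditions are censored, which
  the generators reproduce faithfully.
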