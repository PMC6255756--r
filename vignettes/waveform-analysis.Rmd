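---
title: "Waveform analysis of circadian protein turnover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Waveform analysis of circadian protein turnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circwave)
```

## The model

A clock protein with concentration $x(t)$ obeys the synthesis/turnover
balance
$$\frac{dx}{dt} = g(t) - r(t)\,x(t),$$
with synthesis rate $g(t) \ge 0$ (proportional to the mRNA level $g_m(t)$
through a translation rate $k(t)$, $g = k\,g_m$) and first-order
degradation rate $r(t) \ge 0$.  A circadian protein is periodic,
$x(t) = x(t+T)$ with $T = 24$ h under light–dark cycles, which has two
immediate consequences that this package exploits.

**The waveform bounds the degradation rate.**  Because $g \ge 0$,
$$r(t) \;\ge\; R(t) \equiv \max\{-x'(t)/x(t),\, 0\}$$
for *any* synthesis profile.  The maximum of $R$ over one period,
$r_{\min} = \max_t R(t)$, is the smallest constant degradation rate
compatible with the waveform; it is attained at a single time, the
*hotspot* $t_R$, which lies between the steepest decline of $x$ and its
trough.  A constant rate therefore implies a half-life no longer than
$\ln 2 / r_{\min}$ at every time of day.

**Periodicity fixes the biosynthetic cost.**  Over one period the protein
is synthesized exactly as much as it is degraded, so the cost
$c = \langle g \rangle = \langle r\,x\rangle$ (mean amount made per hour)
is determined by $r$ and $x$.  Under the best constant rate the cost
cannot fall below $c_g = r_{\min}\langle x \rangle$; the *cost reduction*
$(c_g - c)/c_g$ measures the saving achieved when the degradation rate is
rhythmic — small away from the hotspot, large only where the waveform
forces it to be.  Sharp waveforms (large $r_{\min}$) make this saving
substantial, which is the quantitative argument for phase-specific
protein half-lives in plant and mammalian clocks.

## From sampled profiles to rates

`circ_series` holds a sampled periodic time course (times in $(0, T]$,
$t = 0$ aliasing $t = T$), and `fit_periodic_waveform` turns it into a
continuous waveform — a periodic cubic interpolating spline by default
(`stats::splinefun(method = "periodic")`), with a periodic piecewise-linear
fallback for coarse (≥ 4 h) sampling where spline overshoot between
samples is not trustworthy.  Derivatives are taken analytically from the
fitted curve, never by finite differences of raw samples, because
$R = -x'/x$ divides by small trough values and amplifies noise.

Published profiles are normalized by the *spline* peak
(`normalize_to_spline_peak`), so samples straddling the true peak
normalize consistently; the exact spline parameterization behind published
figures is rarely stated, so normalization constants can differ from other
analyses at the percent level.

`lower_bound_profile` evaluates $R$ on a dense grid (0.01 h), refines the
hotspot by local optimization, and reports $r_{\min}$, $t_R$, the
steepest-decline time and the trough.  Ties are broken by the earliest
time in $(0, T]$.  Division is guarded by a floor of $10^{-6}$ times the
peak: a waveform that touches zero has an unbounded $R$ and is refused
with the offending time, rather than silently clipped.

## Reconstructing the full degradation-rate curve

Measured degradation rates (from cycloheximide-chase assays, fitted by
`fit_decay_rate` as a log-linear regression from a stated start time, with
replicate-level slope dispersion) exist only at a few *anchor* times.
The reconstruction inverts the balance equation on the sampling grid:

1. `estimate_translation_constant` computes
   $k_i = [x'(t_i) + r(t_i)x(t_i)]/g_m(t_i)$ at each anchor and averages
   them (unweighted — anchor qualities are rarely comparable enough to
   justify weights); `fit_sinusoidal_translation` offers a rhythmic
   alternative $k(t) = \max\{a\sin(2\pi t/T - \phi) + b, \epsilon_k\}$,
   underdetermined below three anchors, in which case the family over a
   phase grid is returned.
2. `infer_rate_curve` evaluates $r(t) = [k g_m(t) - x'(t)]/x(t)$ on the
   grid (2 h by default, matching the sampling), with measured anchors
   overriding the formula at their grid points.
3. `apply_bounds` caps implausible spikes (at a stated number, at the
   curve's own maximum over a declared window, or at $r_{\min}$) and
   floors the curve at the smallest measured rate.  Flooring *raises* the
   inferred cost, so the resulting cost reduction is conservative.
4. `correct_window` replaces a declared artifact window by the line
   through named anchors (constant extrapolation for a single anchor).
   Artifact windows are configuration inputs chosen per protein by
   inspection, never auto-detected.

Every grid point carries a provenance flag (`anchor`, `inferred`,
`capped_high`, `floored_low`, `corrected_window`), and `run_pipeline`
logs each applied rule so a run is reproducible from its configuration
alone.  When anchors cover a wide span of the cycle (the mammalian PER2
case) `infer_from_anchors_only` skips the mRNA profile entirely:
periodic linear interpolation through the anchors, lifted pointwise to
$R(t)$ so the bound is never violated.  This estimator is deliberately
rough; downstream costs from it should be read with ±20% generosity.

For coarsely sampled data with a full measured rate series (the algal
CCA1/TOC1 case) the shape of $R$ between samples is unreliable, so
`algal_r_min` uses the conservative
$r_{\min} = \min\{\max_t r(t), \max_t R(t)\}$ with a linear waveform fit.

## The two-component feedback theory

The mammalian core loop couples active CLOCK–BMAL1 ($x_A$, written $x$
below) to free PER–CRY ($y$):
$$\frac{dx}{dt} = g_A(t) - [r_0 + k\,y(t)]\,x(t), \qquad
k\,y(t) = \frac{g_A(t) - x'(t)}{x(t)} - r_0 .$$
`simulate_feedback` integrates the full two-state system to its limit
cycle (deSolve, consecutive-period sup-norm residual below $10^{-8}$);
`inhibitor_from_activator` inverts it.  Physical feasibility
($r_0 + ky \ge 0$) bounds the drive from below: $g_{\min} = \max_t x'(t)$
for a constant drive, with the lagged-linear analogue computed by
`feasibility_floor` (closed form available for the analytic sinusoid
$x(t) = -(L/\omega)\cos\omega t + L/\omega + h_0$).

With a *constant* drive the peak of $y$ is squeezed between the hotspot
and the trough of $x$, so the phase difference
$\phi = |\omega(t_y - t_x)|$ is always near anti-phase; for the sinusoid
the closed form is
$\phi = \pi - 2\tan^{-1}[(\sqrt{C^2 - L^2 + g^2} - g)/(C+L)]$ with
$C = h_0\omega + L$.  With an *oscillating* drive
$g_A = \alpha + \beta x(t+\tau)$ the constraint dissolves:
`phase_oscillating_drive` implements the exact peak-time solution (branch
integer chosen so $0 < \omega t_y \le 2\pi$), and sweeping $\alpha$ moves
$\phi$ from near in-phase to near anti-phase.  `classify_ty_regime`
documents the four sign regimes of $(\alpha, 1-\beta\tau)$ under the
small-lag approximation $x(t+\tau) \approx x(t) + \tau x'(t)$; the solver
used for numbers is always the exact pipeline, the approximation is only
the classification device (it is first-order in $\tau$, so regime bounds
are checked with a modest 0.05 h tolerance in the tests).
`half_period_drive` covers lags near $T/2$ through the antisymmetry
$x(t+T/2) \approx J - x(t)$, $J = (2/T)\int_0^T x\,dt$; the antisymmetry
residual is reported, not enforced.

No standard scalar measures "symmetry of a waveform about its peak", so
this package defines one: `symmetry_index` is the RMS of
$w(t_{peak}-s) - w(t_{peak}+s)$ over half a period, normalized by the
peak-to-trough amplitude — zero exactly for any pure sinusoid, and
monotonically decreasing as a constant drive grows and the $x'$ term in
$ky$ becomes negligible.

## Synthetic scenarios and what they do (not) show

`make_scenario` builds fully specified ground-truth systems from named
waveform primitives (constant, sinusoid, half-wave-rectified
`truncated_sinusoid`, `double_gaussian`) and integrates the balance
equation over a burn-in of at least 10 periods to a periodic residual
below $10^{-8}$.  The default mimics a PRR-type plant protein: transcript
peaking mid-day, degradation rate peaking just before the protein trough,
$T = 24$ h, 2-h sampling.  `sample_dataset` applies multiplicative
log-normal noise (unit mean; immunoblot-style proportional error, default
CV 0.05), peak-normalizes, and emits anchors; the scenario seed fully
determines the output.

Two facts are theorems on these scenarios and are tested as such:
$r_{true}(t) \ge R(t)$ everywhere, and
$\langle k g_m\rangle = \langle r x\rangle$ (checked to $10^{-6}$ with
0.002-h quadrature).  Parameter recovery is exact to better than 1%
(sup-norm) for *smooth* noiseless scenarios at 2-h sampling.  Two honest
limitations, documented rather than hidden:

* waveforms with derivative kinks (truncated sinusoids) cannot be
  recovered to 1% from 2-h samples — the error is interpolation, not
  inference, and the recovery tests therefore use smooth scenarios, while
  the bound and conservation theorems are exercised on sharp ones too;
* under 5% multiplicative noise, spline differentiation amplifies error
  near the trough: across 50 seeded replicates the pointwise relative
  error has median ≈ 5% but a heavy tail (90th percentile ≈ 20%).  The
  tests assert the reproducible level (median < 10%, ≥ 90% of grid points
  within 25%).  Real immunoblot data will be at least this hard.

The generator emulates sampling, noise and normalization of published
profiles; it does not emulate cell-population desynchronization,
stochastic kinetics, or detection-limit censoring near troughs, so
passing recovery tests bound methodological error only.

## Packaged example data

The example input profiles under `inst/extdata` are **synthetic
stand-ins**, as their filenames state: smooth control-point waveforms
designed to emulate published PRR7/PRR5/PER2/CCA1/TOC1 profiles — the
sampling regime (2-h grids over $T=24$ h; a dense $T=23.4$ h trace for the
PER2-like case; 4-h grids for the algal case), the shapes (mid-day peaks,
sharp pre-dawn troughs), and the published summary statistics
($r_{\min}$, hotspot time, mean level, anchor rates) — not digitized
source data.  Anchor rates that were never printed (the plant rates at
ZT4/ZT12/ZT19) were fixed once, during fixture construction, at values
consistent with the published bound and costs.  They let every pipeline
stage run and be checked offline; conclusions about real proteins require
real profiles supplied in the same CSV dialect.

## Numerical choices

* Dense grids: 0.1 h for reported curves, 0.01 h for extremum location
  and quadrature (0.002 h where a $10^{-6}$ identity is asserted);
  argmax/argmin ties break to the earliest time in $(0,T]$.
* The $x$-floor for divisions is $10^{-6}$ of the peak; degenerate
  waveforms are errors, not warnings.
* $R$-smoothing (1-h moving window) is opt-in, used for noisy dense
  profiles; when applied, the hotspot is located on the smoothed grid.
* Rates are always per hour; half-life bounds are reported in minutes.
* Light-regime annotations are metadata only and never enter computation;
  dawn is hour 0.
* Reconstruction grids default to the data's own sampling interval; an
  anchor off the grid is assigned to its nearest grid point.
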