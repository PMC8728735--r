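---
title: "Methods: dielectric relaxation and dissolution analysis of amorphous drugs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dielectric relaxation and dissolution analysis of amorphous drugs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amorphkit)
```

# The problem

An amorphous active pharmaceutical ingredient dissolves faster than its
crystal, but it is metastable: its shelf life is governed by molecular
mobility in the glassy state.  Broadband dielectric spectroscopy measures
that mobility directly — the structural (α) relaxation appears as a loss
peak ε″(f) that slows by roughly one decade per few kelvin on cooling
toward the glass transition.  This package implements the standard
analysis chain for such data, plus the intrinsic-dissolution analysis
used to connect solid-state differences to performance: per-temperature
model fits of the loss spectra, extraction of the α-relaxation time map,
its Vogel–Fulcher–Tammann (VFT) parameterization and the dielectric glass
transition temperature, master-curve prediction of relaxation times below
Tg (the aging diagnostic), and windowed intrinsic-dissolution-rate (IDR)
estimation with fold-changes between solid forms.

# Models

## Havriliak–Negami with dc conduction

Each spectrum is fitted with

$$\varepsilon''(\omega) = \frac{\sigma_{DC}}{\varepsilon_0\,\omega}
  \;-\; \mathrm{Im}\!\left[\frac{\Delta\varepsilon}
  {\bigl(1 + (i\omega\tau_{HN})^{a}\bigr)^{b}}\right],$$

with dielectric strength $\Delta\varepsilon > 0$, relaxation time
$\tau_{HN} > 0$, symmetric and asymmetric broadening exponents
$0 < a, b \le 1$ (Debye at $a = b = 1$), and dc conductivity
$\sigma_{DC}/\varepsilon_0 \ge 0$ in s⁻¹.  Design choices:

* **Residuals in log10(loss).**  The curve spans several decades between
  the conductivity tail and the high-frequency flank; linear residuals
  would weight only the peak.
* **Loss-only fitting.**  ε′ is accepted as an optional pass-through
  column by the readers but never enters the objective, so ε∞ does not
  appear in the model.
* **Pure dc conduction.**  The conductivity exponent is fixed at 1; no
  fractional "excess wing" term is offered.
* **Multi-start.**  16 Levenberg–Marquardt starts (`minpack.lm`), shape
  exponents on the grid {1.0, 0.8, 0.6, 0.4} × {1.0, 0.6}, relaxation
  times drawn log-uniformly over the window under a configurable seed
  (default 0), conductivity initialized from the lowest-frequency point
  when the local log-log slope is steeper than −0.8.  Bounds
  $10^{-3} \le a, b \le 1$; ties broken by residual norm, then smaller
  $\tau_{HN}$.

The peak frequency and the α-relaxation time follow in closed form,

$$f_{max} = \frac{1}{2\pi\tau_{HN}}\left[
  \frac{\sin\frac{\pi a}{2+2b}}{\sin\frac{\pi ab}{2+2b}}\right]^{1/a},
\qquad
\tau_\alpha = \frac{1}{2\pi f_{max}},$$

and the two are tested against each other and against a 10⁶-point numeric
argmax.

## The KWW transform

Peak shape is quantified by the stretching exponent β of the
Kohlrausch–Williams–Watts function through its one-sided Fourier
transform,

$$\varepsilon''(\omega) = A \int_0^\infty
  \left(-\frac{d\phi}{dt}\right)\sin(\omega t)\,dt,
  \qquad \phi(t) = e^{-(t/\tau)^\beta},$$

an oscillatory integral with no closed form for $\beta < 1$.  After the
substitution $v = (t/\tau)^\beta$ the integrand becomes
$e^{-v}\sin(x v^{1/\beta})$ with $x = \omega\tau$, and the scheme is:

* $x \ge 3$: the convergent series
  $\sum_k (-1)^{k-1}\frac{\Gamma(k\beta+1)}{k!}\sin(\pi k\beta/2)\,x^{-k\beta}$
  (terms decay superexponentially for $\beta < 1$; at these $x$ there is
  no destructive cancellation).
* $x < 3$: 15-point Gauss–Legendre panels between consecutive zeros of
  the sine factor, with panels capped at width 2 so $e^{-v}$ is resolved
  and a geometrically graded mesh at $v = 0$ where $v^{1/\beta}$ has only
  finitely many bounded derivatives.  When the $e^{-v}$ decay leaves a
  long alternating tail of lobes (small β), the lobe series is truncated
  at 200 terms and accelerated by repeated averaging of partial sums
  (Euler–van Wijngaarden).

Against frozen references computed independently at 40+ significant
digits, the evaluator is accurate to ~1e-11 relative over
$\omega\tau \in [10^{-3}, 10^{3}]$ and $\beta \in [0.3, 1]$; the test
suite asserts 1e-6.  Two global identities are also enforced: the Debye
limit $A\,x/(1+x^2)$ at $\beta = 1$, and the sum rule
$\int \varepsilon''\, d\ln\omega = \frac{\pi}{2}A$ (0.1 %).

`fit_kww()` fits (β, τ, A) in log10 space over a ±2-decade window around
the peak, multi-started over β ∈ {0.3, …, 1.0}.  Conductivity is removed
before fitting, either by subtracting a known (typically HN-fitted)
σ/ε₀, or in masking mode, which bounds σ from the lower envelope of
ε″·ω and drops points where that conductivity could exceed 10 % of the
measured loss.  A peak fully buried under conduction is reported as not
fittable rather than guessed at.

**A caveat used throughout the tests:** the KWW and HN families are
different function spaces.  For a peak generated by an HN model, the
best-fit β depends slightly (≈ ±0.02) on how the fit window is clipped by
the measurement window, even without noise.  The shape-invariance
diagnostic (`shape_invariance_check()`, default spread threshold 0.05) is
therefore exact on KWW-generated ladders but only approximate on
HN-generated ones; a "failed" spread on real or HN-synthetic data at the
2 % noise level indicates window sensitivity of the KWW approximation
before it indicates a true shape change.

## VFT and the glass transition

Measured $\log_{10}\tau_\alpha(T)$ points (≥ 4, spanning ≥ 2 decades) are
fitted with $\tau_\alpha = \tau_\infty\exp[B/(T-T_0)]$ by bounded
Levenberg–Marquardt on log10 times, multi-started over an 11-point $T_0$
grid from 0 K (the Arrhenius limit, which the fit recovers with
$T_0 < 1$ K on Arrhenius data) to 5 K below the lowest temperature.  The
glass transition uses the τ_α = 100 s convention:

$$T_g = T_0 + \frac{B}{\ln(\tau_{ref}/\tau_\infty)},$$

with first-order propagation of the fit covariance.  Note the convention
direction: a *longer* reference time is reached at a *lower* temperature,
so $T_g$ is strictly decreasing in $\tau_{ref}$.  The kinetic fragility
$m = B\,T_g/(\ln 10\,(T_g-T_0)^2)$ is reported as a derived index.

## Master curves below Tg

Below Tg the α peak exits the window and only its high-frequency flank is
measurable.  Under time–temperature superposition (valid when the peak
shape is temperature-invariant, which `shape_invariance_check()` verifies
upstream), a flank can be superposed onto a supercooled-liquid reference
spectrum by a horizontal shift in log frequency.  `estimate_shift()`
minimizes the mean squared difference of log10 loss over the overlap,
with linear interpolation in log-log space, a 0.1-decade coarse pre-scan
over ±8 decades followed by bracketed refinement, conductivity-dominated
points excluded by a local slope ≤ −0.95 criterion, and an optional noise
floor.  No vertical scaling is applied; the residual vertical offset is
reported as a diagnostic.  Sign convention:
$s = \log_{10}(\tau_{target}/\tau_{ref})$, so
$\log_{10}\tau_\alpha(T) = \log_{10}\tau_\alpha(T_{ref}) + s(T)$, and a
slower (glassy) target has a positive shift.

Two practical limits are made explicit:

* **Feasibility.**  A shift close to the window width leaves no overlap;
  solutions pressed against the feasible range at minimal overlap are
  flagged (`boundary = TRUE`).  With a 0.1 Hz–1 MHz window and the
  default generating law, spectra deeper than ~10 K below Tg stop being
  superposable — a physical property of the method, not an implementation
  limit.
* **Information content.**  Deep flanks approach a pure power law, which
  is shift-degenerate; precision comes from the residual curvature of the
  HN/KWW tail within the overlap.

`compare_to_vft()` reports the signed deviation of predicted glassy
$\log_{10}\tau_\alpha$ from the extrapolated VFT law; positive deviations
(slower than extrapolation) are the signature of a more aged, lower
free-energy glass.

## Intrinsic dissolution

The stationary-disc model
$C(t) = C_s\left(1 - e^{-kSt/V}\right)$ has initial slope
$dC/dt|_0 = k S C_s / V$, so the windowed estimator
$\mathrm{IDR} = (V/S)\cdot\hat{\beta}_{OLS}$ recovers $k C_s$ exactly in
the linear regime (and is exact on linear data; both are tested).
Windows are user-specified — defaults 0–15 min (fast-dissolving early
regime), 60–120 min (late regime), 0–120 min (crystalline-like) — and
never inferred from the data, because window choice changes the estimand
on saturating profiles (IDR decreases as the window moves later).
Fold-changes between forms are reported with the conventional rounding of
dissolution studies: nearest integer at ratios ≥ 10, one decimal below.
`detect_regime_change()` fits two unconstrained line segments over every
interior breakpoint with ≥ 3 points per side (exhaustive enumeration, and
tested against an independent naive loop) and declares a kinetic change
only when the residual improves by ≥ 20 % over a single line, with an
absolute floor so exactly-linear data are never flagged.

# The synthetic-data generator

`simulate_spectrum_set()` emulates a heating run on a supercooled
amorphous drug.  All defaults are fixed study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| Tg(τ = 100 s) | 351 K | calibration target of the generating law |
| τ∞ | 1e-14 s | phonon attempt timescale |
| T₀ | 300 K | gives fragility m ≈ 110, typical of van der Waals drug glasses |
| B | (351 − 300)·ln(100/1e-14) ≈ 1879 K | fixed by the two rows above |
| Δε | 7.8 | dielectric strength of the α process |
| (a, b) | (0.88, 0.631) | HN shape whose KWW exponent is 0.62 |
| σ coupling | σ/ε₀ = 0.05/τ_α | one constant ties conduction to structural relaxation; −1 tail visible without burying the coldest peak |
| window | 0.1 Hz–1 MHz, 8 pts/decade | standard BDS frequency range |
| temperatures | 359–381 K, step 2 K | peaks traverse the window |
| noise | 2 % multiplicative log-normal | conservative for a modern BDS analyzer |

Noise is multiplicative and log-normal (mean-one) because loss spans
decades — additive noise would be negligible at the peak and dominant on
the flanks.  With `noise_cv = 0` the simulated spectra equal the
closed-form model to machine precision, and the ladder satisfies
time–temperature superposition exactly, which is what makes the
master-curve stage testable against construction.  The generator omits
secondary (β) relaxations, electrode and Maxwell–Wagner polarization, and
temperature-dependent Δε — real spectra have all four, so passing tests
demonstrate correctness of the estimators under the stated model, not
robustness to every instrumental artifact.

`simulate_dissolution()` uses the closed-form stationary-disc solution
with defaults mirroring a paddle-apparatus run (V = 500 mL, 8 mm disc,
S ≈ 0.5027 cm², samples every 5 min to 120 min, triplicate, 5 %
replicate noise); k and C_s are free parameters of the simulated form.

# Numerical choices and degenerate inputs

* All fits are bounded Levenberg–Marquardt with multi-start; convergence
  flags and per-start diagnostics are kept on the fit objects.
* Seeds: every stochastic component (simulators, start draws) runs under
  an explicit seed through a scope that restores the caller's RNG state;
  pipelines are bit-reproducible given their seed.
* Degenerate inputs raise classed conditions
  (`amorphkit_format_error`, `amorphkit_domain_error`,
  `amorphkit_not_fittable`, `amorphkit_insufficient_data`,
  `amorphkit_insufficient_overlap`) rather than returning silently wrong
  numbers: flank-only spectra are not HN/KWW-fittable unless the peak
  requirement is lifted, VFT refuses < 4 points or < 2 decades,
  temperatures at or below T₀ are undefined, windows with < 3 points are
  rejected, and non-superposable spectra raise or flag as described.
* Problem sizes used by the tests and the acceptance script — a
  12-temperature ladder, four glassy flanks, 10⁶-point argmax oracles,
  10⁴-draw random-search oracles, 100-replicate pilot Monte-Carlo for the
  noisy-recovery tolerances — were chosen to keep the whole suite at a
  few minutes on one CPU while leaving each check far from its tolerance.

# Known limitations

* Per-temperature fitting only; no global (multi-temperature) HN fit.
* No β-relaxation, electrode polarization, or excess-wing modeling; no
  time-domain KWW fitting; β > 1 (compressed exponential) is out of range.
* Master-curve chaining across successive glassy spectra is not enabled
  by default (each flank is shifted directly onto the single reference);
  deep flanks that no longer overlap the reference are flagged, not
  extrapolated.
* The dissolution side models concentration-time data only: no
  UV-calibration processing and no mechanistic model of solvent-mediated
  recrystallization — the breakpoint detector locates, but does not
  explain, a kinetic change.
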