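---
title: "Global kinetic analysis of BLI sensorgrams with profile confidence intervals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global kinetic analysis of BLI sensorgrams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blifit)
options(blifit.verbose = FALSE)
```

## The measurement and the model

Bio-layer interferometry (BLI) records the optical thickness of a sensor
tip as a function of time while an analyte binds to an immobilized ligand
(the association phase, analyte present at concentration $C$) and then
unbinds into buffer (the dissociation phase). For a 1:1 interaction under
pseudo-first-order conditions the association phase approaches its plateau
exponentially with observed rate $k_{obs} = k_{on} C + k_{off}$, and the
dissociation phase decays with rate $k_{off}$.

Two practical complications shape the model `blifit` fits:

* **Probe leak.** When the ligand is His-tagged and captured on a Ni-NTA
  tip, it slowly leaches off the sensor, multiplying the whole signal by a
  slow decay $e^{-k_{leak} t}$.
* **Per-curve optics.** Each sensor tip has its own loading density and
  optical offset, so the amplitude and baseline of each curve are nuisance
  parameters that must be free per curve.

The fitted model for curve $i$ is therefore

$$y^i_{bind}(t) = \left[a^i_{on}\left(1 - e^{-(k_{on} C_i + k_{off})t}\right)
  + b^i_{on}\right] e^{-k_{leak} t}$$
$$y^i_{unbind}(t) = \left[a^i_{off}\, e^{-k_{off} t} + b^i_{off}\right]
  e^{-k_{leak} t}$$

with $t$ restarting at zero at the start of each phase; the leak factor
also uses this phase-local clock in both phases, i.e. leak decay is not
carried over across the phase boundary. A run-wide leak clock would be the
main alternative; we implement the phase-local form because it is the form
the per-phase amplitudes and baselines are defined against, and any
carried-over decay is absorbed by the free $a^i_{off}$, $b^i_{off}$ of the
dissociation phase.

All concentration curves of a dilution series are fit **simultaneously**:
$k_{on}$, $k_{off}$, $k_{leak}$ are shared across curves while
$(a^i_{on}, b^i_{on}, a^i_{off}, b^i_{off})$ are per curve, giving
$4n + 3$ free parameters for $n$ curves (35 for a typical 8-curve series).
Global fitting is what makes weak-binding series identifiable: no single
curve constrains $k_{on}$ and $k_{off}$ separately, but the
concentration-dependence of $k_{obs}$ across the series does. The
equilibrium affinity is derived as $K_D = k_{off}/k_{on}$; smaller $K_D$
is tighter binding.

Units are fixed package-wide: concentrations in µM, time in s, $k_{on}$ in
µM⁻¹s⁻¹, $k_{off}$ and $k_{leak}$ in s⁻¹, $K_D$ in µM. Signal is in
instrument units (nm shift) and treated as an arbitrary linear scale.
Zero-concentration control curves use the same equations ($k_{obs}$
reduces to $k_{off}$); they are not special-cased.

## Fitting

`fit_global()` minimizes the unweighted sum of squared residuals over both
phases of every curve. The problem is *separable*: for fixed rates the
model is linear in all $4n$ amplitudes and baselines, so those are
profiled out exactly (box-constrained linear least squares per phase per
curve) and bounded Levenberg–Marquardt (via `minpack.lm::nls.lm`, with
analytic Jacobians) runs on the three rates alone, followed by a
full-parameter polish. This variable-projection structure avoids the slow
crawl that plain joint descent exhibits along the nearly flat
amplitude–leak directions of this model, and every accepted step decreases
the SSE. Residuals are assembled in a fixed order (curve order,
association before dissociation, time-ascending) so the objective is
bit-reproducible.

Numerical choices:

* **Bounds.** Rates in $[0, 10^3]$ in their stated units (positivity is
  physical); amplitudes in $[0, 10 \cdot \max|y|]$ and baselines in
  $\pm 10 \cdot \max|y|$, wide enough not to distort the profiling below.
* **Scale.** Parameters are optimized on the linear scale with
  non-negativity handled by bounds rather than log-transforms, which keeps
  the fit directly comparable to brute-force grid searches over the rates.
* **Start.** `initial_guess()` reads a provisional observed rate off each
  association phase (half-rise time), regresses $k_{obs}$ on $C$ to start
  $k_{on}$ (slope) and $k_{off}$ (intercept, floored at small positive
  values), starts $k_{leak}$ from the control curve's terminal slope when
  that carries signal (else $10^{-4}$ s⁻¹), and takes baselines and
  amplitudes from the first samples and spans of each phase.
* **Convergence.** Relative SSE-change tolerance $10^{-10}$, iteration
  budget 5000 (the optimizer is called in warm-started rounds of at most
  1024 iterations, its per-call cap). Non-convergence is reported in the
  result, not thrown.
* **Degenerate inputs.** Designs with a single distinct concentration (or
  only controls) are rejected before fitting; non-finite model values
  during optimization raise an error citing the parameter values.

The assumed measurement noise $\sigma_{data}$ is deliberately absent from
the estimation: it scales the chi-squared by a constant, so it affects
neither the optimum nor — because the confidence machinery below uses only
the *ratio* of chi-squareds — any confidence interval. `fit_options()`
accepts it for reporting only, and the test suite asserts the
cancellation numerically.

## Confidence intervals by fixed-parameter profiling

For each of $k_{on}$, $k_{off}$, $K_D$, the fit is repeated with that
single parameter fixed to values on a log-spaced grid spanning a 4-fold
range below and above its best-fit value (41 points by default), all other
parameters refit, warm-started from the global optimum $p_{opt}$ and — as
a pure improvement — from the neighboring grid point's solution when that
has lower SSE. Profiling $K_D$ reparameterizes the model to
$(k_{on}, K_D, k_{leak})$ with $k_{off} := k_{on} K_D$ so the derived
quantity can be held fixed.

Each constrained refit is scored by the normalized chi-squared
$\chi^2_N(p) = \chi^2(p) / \chi^2(p_{opt})$ and accepted while

$$\chi^2_N < 1 + \frac{n}{DF} F_{0.05}(n, DF),$$

where $n$ is the free-parameter count of the full fit and $DF$ the total
number of data points. For the canonical 8-curve series ($n = 35$,
$DF = 2800$) the 95% F quantile is $\approx 1.43$ and the threshold
$\approx 1.018$. Two conventions here follow the profiling procedure this
package implements rather than the textbook F-test: $DF$ is the raw
data-point count (not $DF - n$), and the full parameter count $n$ — not 1 —
is the numerator degrees of freedom even though a single parameter is
profiled. Both make the threshold, and hence the intervals, conservative:
they are upper bounds on the 95% confidence interval. Simulation confirms
this — across 200 synthetic replicates the interval for $k_{on}$ covered
the generating value in every replicate (the single-parameter profile
statistic rarely exceeds $1 + \chi^2_1/(DF-n)$, far below this threshold),
so the intervals over-cover rather than under-cover.

The interval endpoints are the outermost accepted values on each side,
refined by bisection between the last accepted and first rejected values
to $10^{-3}$ relative precision; sides that never cross the threshold
within the 4-fold range are flagged as censored. Results are reported as
"best ± half-width" with the half-width the maximum accepted deviation
(e.g. `0.26 ± 0.02`), plus raw endpoints in machine output.

## The synthetic-data generator

Raw instrument traces are rarely shareable, so `simulate_dataset()`
generates dilution series with the statistical structure the analysis
assumes, and the whole pipeline is validated on them:

* concentrations: a 7-point two-fold dilution from 8 µM plus a 0 µM
  control (8 curves) by default;
* phases of 300 s sampled at 175 uniform points each (2800 points over the
  default series, the size of a typical real run);
* association amplitudes following equilibrium saturation
  $a_{on} = a_{max} C / (C + K_D)$ — the standard binding isotherm, which
  realistically starves the weakest curves of amplitude;
* dissociation amplitude continuous with the noiseless association
  endpoint (optional flag, since the analysis model fits the phases'
  amplitudes independently);
* a default $k_{leak}$ of $5 \times 10^{-4}$ s⁻¹ and additive i.i.d.
  Gaussian noise, default SD 0.5% of $a_{max}$ — declared, realistic
  assumptions where the instrument values are not published;
* a single integer seed from which per-curve noise substreams are derived,
  so extending the series never reshuffles existing curves' noise.

What the generator does *not* emulate: loading/equilibration phases,
baseline drift, spikes, mass-transport limitation, or heterogeneous-ligand
behaviour. Passing round-trip tests therefore demonstrate correctness of
the estimator under its own assumptions — exponential kinetics plus white
Gaussian noise — not robustness to every instrument artefact in real data.
`optonb_scenarios()` provides seven realistic rate sets spanning
$K_D \approx 0.26$–29 µM (the LaM8 anti-mCherry nanobody and its
light-switchable GG15/AK74 variants in dark, lit, and pseudo-lit states)
for stress-testing across the affinity range.

```{r, eval = FALSE}
scen <- optonb_scenarios()[["LaM8"]]
ds   <- simulate_dataset(scen$kin, simulation_design(seed = 1))
fit  <- fit_global(ds)
cis  <- profile_confint(ds, fit)
print(cis[["K_D"]])
```

## Problem sizes used in the tests

The shipped test suite exercises full-size (8-curve, 2800-point) datasets
for the round-trip and recovery checks, and reduced designs — 4 curves of
60 points per phase at 1% noise, 200 replicates — for the coverage study;
profiling tests use 7–11 grid points. These sizes were chosen so the whole
suite probes every claim at meaningful scale while remaining comfortable
to run routinely on a laptop.

## Known limitations

* Strictly 1:1 Langmuir kinetics with a leak factor; no 2:1,
  mass-transport-limited, or heterogeneous models.
* A single local fit from a data-driven start; no multi-start stochastic
  search or Bayesian posterior (the SSE surface of this model is
  well-behaved near physically sensible starts, and the round-trip tests
  confirm recovery from `initial_guess()` across the scenario panel).
* The confidence intervals inherit the conservative threshold convention
  described above: they are reliable upper bounds, not exact 95%
  intervals.
* Concentrations are taken as known exactly; analyte-concentration error
  propagates directly into $k_{on}$.
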