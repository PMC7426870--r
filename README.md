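# blifit

Global kinetic analysis of bio-layer interferometry (BLI) sensorgrams in R.

## What it does, and for whom

BLI (e.g. Octet instruments) measures time-resolved binding curves: an
association phase while an analyte at concentration *C* binds a
sensor-immobilized ligand, then a dissociation phase in buffer. For anyone
measuring 1:1 binding kinetics — antibody/nanobody engineers,
protein-interaction labs — the quantities of interest are the association
rate constant *k*<sub>on</sub> (µM⁻¹s⁻¹), the dissociation rate constant
*k*<sub>off</sub> (s⁻¹), and the affinity
*K*<sub>D</sub> = *k*<sub>off</sub>/*k*<sub>on</sub> (µM).

`blifit` fits an entire dilution series **globally**: the model for curve
*i* is

```
y_bind(t)   = [ a_on_i (1 − e^−(k_on·C_i + k_off)·t) + b_on_i ] · e^−k_leak·t
y_unbind(t) = [ a_off_i e^−k_off·t + b_off_i ] · e^−k_leak·t
```

with the three rates shared across all curves and the per-curve amplitudes
and baselines (`a_on, b_on, a_off, b_off`) free — 4n + 3 parameters for n
curves (35 for a typical 8-curve series with ~2800 data points).
`k_leak` models the slow leak of His-tagged ligand off a Ni-NTA tip as a
multiplicative decay; *t* is phase-local (restarts at 0 in each phase).

95% confidence intervals for *k*<sub>on</sub>, *k*<sub>off</sub>, and
*K*<sub>D</sub> come from fixed-parameter profiling: each parameter is
fixed across a 4-fold range around its best-fit value, everything else is
refit, and values are accepted while the normalized chi-squared
χ²<sub>N</sub> = SSE(p)/SSE(p_opt) stays below the F-statistic threshold

```
χ²_N,thr = 1 + (n/DF) · F_0.05(n, DF)      # ≈ 1.018 at n = 35, DF = 2800
```

A synthetic sensorgram generator (dilution series, saturating amplitudes,
probe leak, Gaussian noise) plus a panel of realistic rate scenarios
(`optonb_scenarios()`: the LaM8 anti-mCherry nanobody and light-switchable
OptoNB variants, K_D ≈ 0.26–29 µM) make the whole pipeline testable without
instrument data. See the vignette in `vignettes/` for the model,
assumptions, and numerical choices.

## Worked example

Simulate an 8-curve dilution series (two-fold from 8 µM plus a 0 µM
control, 0.5% noise) with the wild-type LaM8 rates, fit it, and profile
the CIs:

```r
library(blifit)
scen <- optonb_scenarios()[["LaM8"]]      # k_on 0.072, k_off 0.019
ds   <- simulate_dataset(scen$kin, simulation_design(seed = 1))
fit  <- fit_global(ds)
print(fit)
#> Global BLI fit: 35 free parameters, 2800 data points
#>   k_on  = 0.07181 uM^-1 s^-1
#>   k_off = 0.01896 s^-1
#>   k_leak = 0.000499 s^-1
#>   K_D   = 0.264 uM
#>   SSE = 0.0667706, converged = TRUE (67 iterations)

cis <- profile_confint(ds, fit, n_grid = 21)
for (ci in cis) print(ci)
#> k_on: 0.072 ± 0.002  [0.06959, 0.0741]
#> k_off: 0.0190 ± 0.0003  [0.01869, 0.01924]
#> K_D: 0.26 ± 0.01  [0.2548, 0.2737]
```

The fit recovers the generating rates within their confidence intervals;
`0.26 ± 0.01 µM` is the affinity with the half-width being the largest
accepted deviation under the χ²<sub>N</sub> threshold (here 1.0178).

The same steps run from a shell via the bundled entry point
(`inst/scripts/blifit`):

```sh
blifit simulate --scenario LaM8 --seed 1 --out lam8.csv
blifit fit      --in lam8.csv --out lam8_report.json
blifit profile  --in lam8.csv --report lam8_cis.json --params kon,koff,kd
blifit compare  --a dark_report.json --b lit_report.json
```

Sensorgrams travel as long-format CSV
(`curve_id, phase, time_s, signal, concentration_uM`); reports as CSV/JSON
with a JSON run manifest for provenance.

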