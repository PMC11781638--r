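# smstoch

Stochastic soil-moisture dynamics in the crop root zone: the marked-Poisson
water-balance jump process (the Laio model of ecohydrology), its closed-form
steady-state probability density of relative soil moisture, a Monte-Carlo
simulator that serves as an independent oracle for that density, and the
surrounding analysis pipeline — rainfall-climate estimation, layered
soil-moisture statistics, Nash–Sutcliffe/MAE/RMSE validation, and ±10%
local parameter sensitivity.

The package is written for agro- and ecohydrologists who want to
characterize growing-season soil-moisture regimes probabilistically rather
than deterministically: given a soil (porosity *n*, root-zone depth *Zr*,
conductivity *Ks*, pore parameter *β*, thresholds *Sh < Sw < S\* < Sfc*), a
crop (*Emax*, *Ew*, interception *Δ*) and a rainfall climate (storm
frequency *λ*, mean storm depth *α*), it returns the stationary density
*p(s)* of relative saturation *s = θ/n*,

```
nZr ds/dt = φ[s;t] − E(s) − L(s),      p(s) ∝ c ρ(s)^{-1} e^{−γs + λ′∫ds/ρ(s)}
```

with piecewise-linear evapotranspiration *E(s)*, exponential deep
percolation *L(s)* above field capacity, γ = nZr/α and λ′ = λe^{−Δ/α}.

## Worked example

The packaged maize parameter record for the Wanjia experimental station
(Songnen Plain) is available as `wanjia_params()`. With soil evaporation
read as 5% of *Emax* (see the vignette for the parameter-record
ambiguities):

```r
library(smstoch)

p <- wanjia_params(Ew = 0.0186)
curve <- soil_moisture_pdf(p)
curve
#> Steady-state soil-moisture density: peak 10.95 at s = 0.4008;
#> 90% interval [0.355, 0.4774] (broadness 0.1224)
```

The growing-season maize soil moisture is thus concentrated in a single
mode near *s* ≈ 0.40 (θ ≈ 0.19): transpiration holds the root zone between
the wilting point and the stress onset, and 90% of days fall in
*s* ∈ [0.355, 0.477].

The Monte-Carlo simulator reproduces the same distribution from the daily
water balance, with a full per-day ledger:

```r
traj <- simulate_soil_moisture(p, days = 2e5, seed = 42)
ks_distance(traj$s[traj$day > 365], curve)
#> [1] 0.01545801
compare_pdfs(curve, empirical_pdf(traj))$nse
#> [1] 0.9986452
```

Local sensitivity of the density to each parameter (±10%, one at a time):

```r
sens <- local_sensitivity(p, parameters = c("alpha", "delta"))
sens[, c("parameter", "direction", "d_peak_value", "d_peak_s", "class")]
#>   parameter direction d_peak_value  d_peak_s  class
#> 1     alpha         +   -10.844413  4.781987 strong
#> 2     alpha         -    13.794622 -4.723330 strong
#> 3     delta         +     2.170733 -1.411222   weak
#> 4     delta         -    -2.119450  1.469451   weak
```

Mean storm depth α is the dominant control: 10% less rain per storm raises
the peak by ~14% and shifts it dry-ward, while canopy interception barely
matters. Synthetic generators (`generate_precipitation()`,
`generate_moisture_observations()`) emulate the station inputs so the whole
pipeline — including `estimate_rainfall_params()`, `precip_trend()`,
`moisture_summary_table()` and `compare_pdfs()` — runs without field data;
the `cmd_*()` functions and `inst/scripts/smstoch-cli.R` expose each stage
over a JSON/YAML run configuration.

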