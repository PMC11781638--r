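Package: smstoch
Type: Package
Title: Stochastic Soil-Moisture Dynamics in the Crop Root Zone
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Point-scale stochastic modelling of growing-season soil moisture
    in rain-fed cropland. Implements the Laio-type water-balance jump process
    driven by marked-Poisson rainfall (Poisson storm arrivals with exponential
    depths, canopy interception, saturation-excess runoff, piecewise-linear
    evapotranspiration and exponential deep percolation), its closed-form
    steady-state probability density p(s) of relative soil moisture, a
    Monte-Carlo daily water-balance simulator with full per-day ledger,
    rainfall and layered soil-moisture statistics, Nash-Sutcliffe/MAE/RMSE
    model validation, one-at-a-time local parameter sensitivity analysis, and
    synthetic-data generators for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
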