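# shared fixtures: the maize study-site parameter set and a generator of
# random valid parameter sets spanning realistic crop-soil conditions

table2 <- function(...) wanjia_params(...)

# parameter set under which the analytic curve is sharply unimodal inside
# the transpiration regime (soil evaporation read as 5% of Emax)
table2_unimodal <- function() wanjia_params(Ew = 0.0186)

random_valid_params <- function() {
  n <- runif(1, 0.35, 0.55)
  Zr <- runif(1, 30, 150)
  sh <- runif(1, 0.05, 0.25)
  sw <- sh + runif(1, 0.03, 0.15)
  sstar <- sw + runif(1, 0.2, 0.45)
  sfc <- min(sstar + runif(1, 0.02, 0.15), 0.95)
  if (sfc <= sstar) sfc <- (sstar + 1) / 2
  Emax <- runif(1, 0.2, 0.6)
  model_params(
    soil = soil_params(n = n, Zr = Zr, Ks = runif(1, 20, 200),
                       beta = runif(1, 9, 16)),
    thresholds = moisture_thresholds(sh, sw, sstar, sfc),
    veg = veg_params(Emax = Emax, Ew = runif(1, 0.02, 0.5) * Emax,
                     delta = runif(1, 0, 0.3)),
    rain = rainfall_params(alpha = runif(1, 0.2, 2), lam = runif(1, 0.1, 0.9))
  )
}

# independent trapezoid integral over a density grid
trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))
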