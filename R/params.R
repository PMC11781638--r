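#' Soil physical parameters
#'
#' Bundle the soil properties entering the water balance: porosity, root-zone
#' depth, saturated hydraulic conductivity and the pore-size distribution
#' parameter of the percolation law.
#'
#' @param n Soil porosity, dimensionless fraction in (0, 1).
#' @param Zr Root-zone depth (cm).
#' @param Ks Saturated hydraulic conductivity (cm/day).
#' @param beta Pore-size distribution parameter (dimensionless). Related to
#'   the pore-aperture distribution index by `beta = 2 * b + 4`.
#' @param b Optional pore-aperture distribution index; when supplied it must
#'   be consistent with `beta` to within 1e-9.
#' @return An object of class `sm_soil`.
#' @export
#' @examples
#' soil_params(n = 0.47, Zr = 80, Ks = 80, beta = 13.8)
soil_params <- function(n, Zr, Ks, beta, b = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, is.numeric(Zr), length(Zr) == 1L,
            is.numeric(Ks), length(Ks) == 1L, is.numeric(beta), length(beta) == 1L)
  if (!is.finite(n) || n <= 0 || n >= 1) stop("porosity n must lie in (0, 1)")
  if (!is.finite(Zr) || Zr <= 0) stop("root-zone depth Zr must be positive")
  if (!is.finite(Ks) || Ks <= 0) stop("saturated conductivity Ks must be positive")
  if (!is.finite(beta) || beta <= 0) stop("pore-size parameter beta must be positive")
  if (!is.null(b)) {
    if (abs(beta - (2 * b + 4)) > 1e-9)
      stop("inconsistent pore parameters: beta must equal 2*b + 4")
  }
  structure(list(n = n, Zr = Zr, Ks = Ks, beta = beta, b = b),
            class = "sm_soil")
}

#' Critical soil-moisture thresholds
#'
#' The four relative-saturation thresholds that shape the loss function:
#' hygroscopic point `sh` (no losses below it), wilting point `sw` (plant
#' transpiration ceases; only soil evaporation remains), onset of water
#' stress `sstar` (evapotranspiration falls below its maximum), and field
#' capacity `sfc` (deep percolation starts above it).
#'
#' @param sh,sw,sstar,sfc Relative saturations, strictly ordered
#'   `0 < sh < sw < sstar < sfc < 1`.
#' @return An object of class `sm_thresholds`.
#' @export
moisture_thresholds <- function(sh, sw, sstar, sfc) {
  v <- c(sh = sh, sw = sw, sstar = sstar, sfc = sfc)
  if (!all(is.finite(v))) stop("thresholds must be finite")
  if (!(0 < sh && sh < sw && sw < sstar && sstar < sfc && sfc < 1))
    stop("thresholds must satisfy 0 < sh < sw < sstar < sfc < 1")
  structure(as.list(v), class = "sm_thresholds")
}

#' Vegetation parameters
#'
#' @param Emax Maximum daily evapotranspiration (cm/day), reached at and
#'   above the water-stress onset.
#' @param Ew Soil evaporation at the wilting point (cm/day), `0 <= Ew <= Emax`.
#' @param delta Canopy interception threshold (cm): storm depth removed by
#'   the canopy before water reaches the soil.
#' @return An object of class `sm_veg`.
#' @export
veg_params <- function(Emax, Ew, delta) {
  if (!is.finite(Emax) || Emax <= 0) stop("Emax must be positive")
  if (!is.finite(Ew) || Ew < 0 || Ew > Emax) stop("Ew must satisfy 0 <= Ew <= Emax")
  if (!is.finite(delta) || delta < 0) stop("interception delta must be >= 0")
  structure(list(Emax = Emax, Ew = Ew, delta = delta), class = "sm_veg")
}

#' Rainfall climate parameters
#'
#' Marked-Poisson storm model: arrivals at frequency `lam` (1/day), depths
#' exponential with mean `alpha` (cm).
#'
#' @param alpha Mean storm depth (cm), `> 0`.
#' @param lam Storm arrival frequency (1/day), `> 0`.
#' @return An object of class `sm_rain`.
#' @export
rainfall_params <- function(alpha, lam) {
  if (!is.finite(alpha) || alpha <= 0) stop("mean event depth alpha must be positive")
  if (!is.finite(lam) || lam <= 0) stop("event frequency lam must be positive")
  structure(list(alpha = alpha, lam = lam), class = "sm_rain")
}

#' Full model parameter set
#'
#' Single source of truth for all equations: soil, thresholds, vegetation and
#' rainfall parameters plus the convention used for the normalized loss rates
#' eta and eta_w.
#'
#' `eta_convention = "standard"` assigns `eta = Emax/(n*Zr)` and
#' `eta_w = Ew/(n*Zr)` (the assignment consistent with the derivation of the
#' steady-state density, and the only one the Monte-Carlo simulator can
#' match); `"as_printed"` exchanges the two, matching a variant typesetting
#' of the derived-parameter definitions found in parts of the literature.
#'
#' @param soil An [soil_params()] object.
#' @param thresholds A [moisture_thresholds()] object.
#' @param veg A [veg_params()] object.
#' @param rain A [rainfall_params()] object.
#' @param eta_convention `"standard"` (default) or `"as_printed"`.
#' @return An object of class `sm_params`.
#' @export
model_params <- function(soil, thresholds, veg, rain,
                         eta_convention = c("standard", "as_printed")) {
  stopifnot(inherits(soil, "sm_soil"), inherits(thresholds, "sm_thresholds"),
            inherits(veg, "sm_veg"), inherits(rain, "sm_rain"))
  eta_convention <- match.arg(eta_convention)
  structure(list(soil = soil, thresholds = thresholds, veg = veg, rain = rain,
                 eta_convention = eta_convention),
            class = "sm_params")
}

#' @export
print.sm_params <- function(x, ...) {
  cat("Stochastic soil-moisture model parameters\n")
  cat(sprintf("  soil:  n=%.3g Zr=%.4g cm  Ks=%.4g cm/d  beta=%.4g\n",
              x$soil$n, x$soil$Zr, x$soil$Ks, x$soil$beta))
  cat(sprintf("  thresholds: sh=%.3g sw=%.3g s*=%.3g sfc=%.3g\n",
              x$thresholds$sh, x$thresholds$sw, x$thresholds$sstar, x$thresholds$sfc))
  cat(sprintf("  veg:   Emax=%.4g Ew=%.4g cm/d  delta=%.3g cm\n",
              x$veg$Emax, x$veg$Ew, x$veg$delta))
  cat(sprintf("  rain:  alpha=%.4g cm  lambda=%.4g /d   (eta convention: %s)\n",
              x$rain$alpha, x$rain$lam, x$eta_convention))
  invisible(x)
}

#' Maize parameter set for the Wanjia station study site
#'
#' The declared growing-season parameter record for the maize root zone at
#' the Wanjia experimental station (Songnen Plain): sandy-loam black soil,
#' 80 cm root zone, temperate monsoon rainfall climate. Arguments allow the
#' two readings of the rainfall depth parameter (mean event depth vs mean
#' daily depth) and of soil evaporation (the declared table value vs 5% of
#' Emax) to be probed explicitly.
#'
#' @param Ew Soil evaporation at wilting (cm/day). Default 0.186, the
#'   declared record; 0.0186 (= 5% of Emax) is the main alternative reading.
#' @param alpha Mean storm depth (cm). Default 0.371; pass
#'   `0.371 / 0.485` to read the declared value as a mean daily depth
#'   converted to mean event depth.
#' @param eta_convention Passed to [model_params()].
#' @return An `sm_params` object.
#' @export
#' @examples
#' p <- wanjia_params()
#' derive_params(p)
wanjia_params <- function(Ew = 0.186, alpha = 0.371,
                          eta_convention = c("standard", "as_printed")) {
  model_params(
    soil = soil_params(n = 0.47, Zr = 80, Ks = 80, beta = 13.8),
    thresholds = moisture_thresholds(sh = 0.21, sw = 0.29, sstar = 0.71, sfc = 0.76),
    veg = veg_params(Emax = 0.372, Ew = Ew, delta = 0.15),
    rain = rainfall_params(alpha = alpha, lam = 0.485),
    eta_convention = match.arg(eta_convention)
  )
}

#' Derived model parameters
#'
#' Computes the normalized loss rates and rainfall parameters entering the
#' steady-state density:
#' `eta = Emax/(n*Zr)`, `eta_w = Ew/(n*Zr)` (exchanged under
#' `eta_convention = "as_printed"`),
#' `m = Ks / (n*Zr*(exp(beta*(1-sfc)) - 1))`,
#' `gamma = n*Zr/alpha`, `lam_prime = lam*exp(-delta/alpha)`, and the
#' normalization constant `c` of the density (see [normalize_pdf()]).
#'
#' @param p An [model_params()] object.
#' @param compute_c Compute the normalization constant (default `TRUE`); set
#'   `FALSE` to get the raw derived parameters only.
#' @return An object of class `sm_derived`: list with elements `eta`,
#'   `eta_w`, `m`, `gamma`, `lam_prime`, `c` and `log_c`.
#' @export
derive_params <- function(p, compute_c = TRUE) {
  stopifnot(inherits(p, "sm_params"))
  nZr <- p$soil$n * p$soil$Zr
  e_leak <- exp(p$soil$beta * (1 - p$thresholds$sfc))
  if (!is.finite(e_leak))
    stop("beta*(1 - sfc) overflows exp(); leakage scale m is not finite")
  if (p$eta_convention == "standard") {
    eta <- p$veg$Emax / nZr
    eta_w <- p$veg$Ew / nZr
  } else {
    eta <- p$veg$Ew / nZr
    eta_w <- p$veg$Emax / nZr
  }
  if (eta == eta_w)
    stop("degenerate loss rates: eta and eta_w must differ")
  dp <- structure(list(
    eta = eta, eta_w = eta_w,
    m = p$soil$Ks / (nZr * (e_leak - 1)),
    gamma = nZr / p$rain$alpha,
    lam_prime = p$rain$lam * exp(-p$veg$delta / p$rain$alpha),
    c = NA_real_, log_c = NA_real_
  ), class = "sm_derived")
  if (compute_c) {
    cc <- normalize_pdf(dp, p)
    dp$c <- cc
    dp$log_c <- attr(cc, "log_c")
  }
  dp
}

#' @export
print.sm_derived <- function(x, ...) {
  cat(sprintf(
    "Derived parameters: eta=%.6g eta_w=%.6g m=%.6g /d  gamma=%.5g  lam'=%.5g /d  c=%.6g\n",
    x$eta, x$eta_w, x$m, x$gamma, x$lam_prime, x$c))
  invisible(x)
}

# flat document keys used for config round-trips (units: cm, day)
.param_keys <- c("n", "Zr", "beta", "Sh", "Sw", "Sstar", "Sfc", "Ks",
                 "Delta", "Emax", "Ew", "alpha", "lambda")

#' Read and write model parameters as flat JSON/YAML documents
#'
#' The document is keyed by the conventional parameter symbols
#' (`n, Zr, beta, Sh, Sw, Sstar, Sfc, Ks, Delta, Emax, Ew, alpha, lambda`,
#' optional `eta_convention`), with units fixed to cm and day and
#' dimensionless saturations.
#'
#' @param path File path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return `read_model_params()` returns an `sm_params` object;
#'   `write_model_params()` returns `path` invisibly.
#' @export
read_model_params <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  model_params_from_list(doc)
}

#' @rdname read_model_params
#' @param p An `sm_params` object.
#' @export
write_model_params <- function(p, path) {
  stopifnot(inherits(p, "sm_params"))
  doc <- list(n = p$soil$n, Zr = p$soil$Zr, beta = p$soil$beta,
              Sh = p$thresholds$sh, Sw = p$thresholds$sw,
              Sstar = p$thresholds$sstar, Sfc = p$thresholds$sfc,
              Ks = p$soil$Ks, Delta = p$veg$delta, Emax = p$veg$Emax,
              Ew = p$veg$Ew, alpha = p$rain$alpha, lambda = p$rain$lam,
              eta_convention = p$eta_convention)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname read_model_params
#' @param doc A named list with the flat parameter keys.
#' @export
model_params_from_list <- function(doc) {
  missing_keys <- setdiff(.param_keys, names(doc))
  if (length(missing_keys))
    stop("parameter document is missing keys: ", paste(missing_keys, collapse = ", "))
  num <- function(k) {
    v <- doc[[k]]
    if (!is.numeric(v) || length(v) != 1L)
      stop("parameter '", k, "' must be a single number")
    v
  }
  model_params(
    soil = soil_params(n = num("n"), Zr = num("Zr"), Ks = num("Ks"),
                       beta = num("beta")),
    thresholds = moisture_thresholds(sh = num("Sh"), sw = num("Sw"),
                                     sstar = num("Sstar"), sfc = num("Sfc")),
    veg = veg_params(Emax = num("Emax"), Ew = num("Ew"), delta = num("Delta")),
    rain = rainfall_params(alpha = num("alpha"), lam = num("lambda")),
    eta_convention = if (is.null(doc$eta_convention)) "standard" else doc$eta_convention
  )
}
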