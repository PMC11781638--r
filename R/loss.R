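#' Evapotranspiration loss rate
#'
#' Piecewise-linear evapotranspiration as a function of relative soil
#' moisture: zero up to the hygroscopic point, rising linearly to the soil
#' evaporation rate `Ew` at the wilting point, then linearly to `Emax` at the
#' water-stress onset, and constant at `Emax` above it. Continuous
#' everywhere.
#'
#' @param s Relative saturation(s) in `[0, 1]`.
#' @param p An [model_params()] object.
#' @return Evapotranspiration rate (cm/day), vectorized over `s`.
#' @export
#' @examples
#' p <- wanjia_params()
#' evapotranspiration_rate(c(0.21, 0.29, 0.5, 0.9), p)
evapotranspiration_rate <- function(s, p) {
  stopifnot(inherits(p, "sm_params"))
  .check_s(s)
  th <- p$thresholds
  v <- p$veg
  out <- numeric(length(s))
  i <- s > th$sh & s <= th$sw
  out[i] <- v$Ew * (s[i] - th$sh) / (th$sw - th$sh)
  i <- s > th$sw & s <= th$sstar
  out[i] <- v$Ew + (v$Emax - v$Ew) * (s[i] - th$sw) / (th$sstar - th$sw)
  out[s > th$sstar] <- v$Emax
  out
}

#' Deep-percolation (leakage) loss rate
#'
#' Exponential percolation above field capacity:
#' `L(s) = Ks * (exp(beta*(s - sfc)) - 1) / (exp(beta*(1 - sfc)) - 1)` for
#' `s > sfc`, zero below. Satisfies `L(sfc) = 0` and `L(1) = Ks`.
#'
#' @inheritParams evapotranspiration_rate
#' @return Leakage rate (cm/day), vectorized over `s`.
#' @export
leakage_rate <- function(s, p) {
  stopifnot(inherits(p, "sm_params"))
  .check_s(s)
  sfc <- p$thresholds$sfc
  beta <- p$soil$beta
  out <- numeric(length(s))
  i <- s > sfc
  out[i] <- p$soil$Ks * expm1(beta * (s[i] - sfc)) / expm1(beta * (1 - sfc))
  out
}

#' Total normalized loss rate
#'
#' The soil-moisture loss function `rho(s) = (E(s) + L(s)) / (n * Zr)`
#' (1/day): evapotranspiration plus deep percolation, normalized by the
#' root-zone storage capacity.
#'
#' @inheritParams evapotranspiration_rate
#' @return Normalized loss rate (1/day), vectorized over `s`.
#' @export
total_loss_rate <- function(s, p) {
  (evapotranspiration_rate(s, p) + leakage_rate(s, p)) / (p$soil$n * p$soil$Zr)
}

.check_s <- function(s) {
  if (!is.numeric(s) || anyNA(s) || any(s < 0 | s > 1))
    stop("relative saturation s must lie in [0, 1]")
  invisible(s)
}
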