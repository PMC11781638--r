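# Closed-form steady-state density of relative soil moisture.
#
# The stationary solution of the Chapman-Kolmogorov forward equation for the
# rainfall-driven jump process has four regimes joined continuously at the
# wilting point, the stress onset and field capacity.  All evaluation is done
# in log space: the factor exp(-gamma*s) with gamma = n*Zr/alpha ~ O(100)
# underflows long before the normalized density does.

# log of the unnormalized density (c = 1), vectorized; -Inf for s <= sh
.log_ps_unnorm <- function(s, dp, p) {
  th <- p$thresholds
  sh <- th$sh; sw <- th$sw; sstar <- th$sstar; sfc <- th$sfc
  eta <- dp$eta; etaw <- dp$eta_w; m <- dp$m
  gam <- dp$gamma; lamp <- dp$lam_prime
  beta <- p$soil$beta
  # constant picked up crossing the (sw, sstar] regime, reused above sstar
  A <- (lamp * (sstar - sw) / (eta - etaw)) * log(eta / etaw)
  out <- rep(-Inf, length(s))

  i <- s > sh & s <= sw
  if (any(i))
    out[i] <- -log(etaw) +
      (lamp * (sw - sh) / etaw - 1) * log((s[i] - sh) / (sw - sh)) -
      gam * s[i]

  i <- s > sw & s <= sstar
  if (any(i))
    out[i] <- -log(etaw) +
      (lamp * (sstar - sw) / (eta - etaw) - 1) *
        log1p((eta / etaw - 1) * (s[i] - sw) / (sstar - sw)) -
      gam * s[i]

  i <- s > sstar & s <= sfc
  if (any(i))
    out[i] <- -log(eta) - gam * s[i] + (lamp / eta) * (s[i] - sstar) + A

  i <- s > sfc & s <= 1
  if (any(i)) {
    # log of eta*e^{beta s} / ((eta - m) e^{beta sfc} + m e^{beta s}),
    # written against the factor e^{beta s} for stability at large beta*s
    lr <- log(eta) - log(m + (eta - m) * exp(-beta * (s[i] - sfc)))
    out[i] <- -log(eta) - (beta + gam) * s[i] + beta * sfc +
      (lamp / (beta * (eta - m)) + 1) * lr +
      A + (lamp / eta) * (sfc - sstar)
  }
  out
}

#' Unnormalized steady-state density
#'
#' Evaluates the four-regime closed-form stationary density of relative soil
#' moisture with normalization constant set to 1. Returns 0 for `s <= sh`.
#'
#' @param s Relative saturation(s) in `[0, 1]`.
#' @param dp An [derive_params()] object (the constant `c` is not used).
#' @param p The [model_params()] object `dp` was derived from.
#' @return Density values up to the normalization constant.
#' @export
unnormalized_pdf <- function(s, dp, p) {
  stopifnot(inherits(dp, "sm_derived"), inherits(p, "sm_params"))
  .check_s(s)
  exp(.log_ps_unnorm(s, dp, p))
}

#' Normalization constant of the steady-state density
#'
#' Computes `c` such that the density integrates to one over `(sh, 1]`.
#' Adaptive quadrature is split at the regime boundaries (`sw`, `sstar`,
#' `sfc`) and performed on the log-rescaled integrand so that the result is
#' finite even when the unnormalized density under- or overflows.
#'
#' @inheritParams unnormalized_pdf
#' @return The constant `c` (numeric scalar) with attribute `"log_c"`.
#' @export
normalize_pdf <- function(dp, p) {
  stopifnot(inherits(dp, "sm_derived"), inherits(p, "sm_params"))
  th <- p$thresholds
  bounds <- c(th$sh, th$sw, th$sstar, th$sfc, 1)
  # rescale by the running maximum of log density over a coarse probe grid
  probe <- .pdf_grid(p, n_per_regime = 200L)
  lp <- .log_ps_unnorm(probe, dp, p)
  M <- max(lp[is.finite(lp)])
  if (!is.finite(M))
    stop("steady-state density is not finite anywhere on (sh, 1]")
  total <- 0
  for (k in seq_len(4L)) {
    if (k == 1L) {
      # the first regime behaves like K*(s - sh)^(a - 1)*exp(-gamma*s) near
      # sh; substitute s = sh + (sw - sh)*u^kk to tame the singularity, cut
      # at a floating-point-representable s1 and add the power-law head
      # below it in closed form
      kk <- .sing_power(dp, p)
      w <- th$sw - th$sh
      a <- dp$lam_prime * w / dp$eta_w
      u1 <- 1e-8^(1 / kk)
      s1 <- th$sh + w * 1e-8
      head <- exp(.log_ps_unnorm(s1, dp, p) - M) * (s1 - th$sh) / a
      f <- function(u) exp(.log_ps_unnorm(th$sh + w * u^kk, dp, p) - M +
                             log(kk * w) + (kk - 1) * log(u))
      lim <- c(u1, 1)
    } else {
      head <- 0
      f <- function(x) exp(.log_ps_unnorm(x, dp, p) - M)
      lim <- bounds[k + c(0L, 1L)]
    }
    piece <- head + tryCatch(
      # after rescaling by M the total is O(1); an absolute floor stops the
      # quadrature from chasing relative accuracy on negligible regimes
      integrate(f, lim[1L], lim[2L],
                rel.tol = 1e-10, abs.tol = 1e-13, subdivisions = 500L)$value,
      error = function(e)
        stop("quadrature failed on regime (", bounds[k], ", ", bounds[k + 1L],
             "]: ", conditionMessage(e)))
    if (!is.finite(piece))
      stop("non-finite integral on regime (", bounds[k], ", ",
           bounds[k + 1L], "]")
    total <- total + piece
  }
  log_c <- -(M + log(total))
  structure(exp(log_c), log_c = log_c)
}

# power of the grid clustering toward sh: the first regime goes like
# (s - sh)^(a - 1) with a = lam'(sw - sh)/eta_w, so a mapping s = sh + w*u^k
# with k >= 1/a keeps the transformed integrand bounded
.sing_power <- function(dp, p) {
  a <- dp$lam_prime * (p$thresholds$sw - p$thresholds$sh) / dp$eta_w
  min(max(2, ceiling(1.5 / max(a, 0.02))), 80)
}

# evaluation grid concatenated over regimes; power-law clustering toward sh
# where the first regime can be steep or integrably singular
.pdf_grid <- function(p, n_per_regime = 2500L, sing_k = 2) {
  th <- p$thresholds
  u <- seq(0, 1, length.out = n_per_regime)
  g1 <- th$sh + (th$sw - th$sh) * u^sing_k
  g2 <- seq(th$sw, th$sstar, length.out = n_per_regime)
  g3 <- seq(th$sstar, th$sfc, length.out = n_per_regime)
  g4 <- seq(th$sfc, 1, length.out = n_per_regime)
  unique(c(g1, g2, g3, g4))
}

#' Analytic steady-state probability density curve
#'
#' Builds the normalized steady-state density of relative soil moisture on a
#' regime-aware grid over `(sh, 1]`, together with its peak and central 90%
#' probability interval.
#'
#' @param p An [model_params()] object.
#' @param dp Optional pre-computed [derive_params()] result.
#' @param n_per_regime Grid points per regime (default 2500).
#' @return An object of class `sm_pdf`: list with elements `s`, `density`,
#'   `c`, `log_c`, `peak_s`, `peak_value`, `interval_90` (named `lo`, `hi`),
#'   `broadness`, `params`, `derived`.
#' @export
#' @examples
#' curve <- soil_moisture_pdf(wanjia_params(Ew = 0.0186))
#' curve$peak_s
soil_moisture_pdf <- function(p, dp = NULL, n_per_regime = 2500L) {
  stopifnot(inherits(p, "sm_params"))
  if (is.null(dp)) dp <- derive_params(p, compute_c = TRUE)
  if (!is.finite(dp$log_c)) {
    cc <- normalize_pdf(dp, p)
    dp$c <- cc; dp$log_c <- attr(cc, "log_c")
  }
  s <- .pdf_grid(p, n_per_regime, sing_k = .sing_power(dp, p))
  dens <- exp(.log_ps_unnorm(s, dp, p) + dp$log_c)
  curve <- structure(list(
    s = s, density = dens, c = dp$c, log_c = dp$log_c,
    peak_s = NA_real_, peak_value = NA_real_,
    interval_90 = c(lo = NA_real_, hi = NA_real_), broadness = NA_real_,
    params = p, derived = dp
  ), class = "sm_pdf")
  d <- pdf_descriptors(curve)
  curve$peak_s <- d$peak_s
  curve$peak_value <- d$peak_value
  curve$interval_90 <- c(lo = d$lo, hi = d$hi)
  curve$broadness <- d$broadness
  curve
}

#' @export
print.sm_pdf <- function(x, ...) {
  cat(sprintf(
    "Steady-state soil-moisture density: peak %.4g at s = %.4g; 90%% interval [%.4g, %.4g] (broadness %.4g)\n",
    x$peak_value, x$peak_s, x$interval_90[["lo"]], x$interval_90[["hi"]],
    x$broadness))
  invisible(x)
}

#' Peak and probability-interval descriptors of a density curve
#'
#' For analytic curves the peak is located by grid argmax refined by bounded
#' scalar maximization inside the containing regime (tolerance 1e-8 in `s`,
#' ties broken toward the smallest `s`); the interval is the central 90%
#' probability interval (5th and 95th percentiles) obtained by numeric CDF
#' inversion. For empirical (histogram) densities the same descriptors are
#' computed from bin probabilities.
#'
#' @param curve An `sm_pdf` or `sm_empirical_pdf` object.
#' @param probs Tail probabilities of the central interval (default
#'   `c(0.05, 0.95)`).
#' @return A list with `peak_s`, `peak_value`, `lo`, `hi`, `broadness`.
#' @export
pdf_descriptors <- function(curve, probs = c(0.05, 0.95)) {
  UseMethod("pdf_descriptors")
}

#' @export
pdf_descriptors.sm_pdf <- function(curve, probs = c(0.05, 0.95)) {
  p <- curve$params
  dp <- curve$derived
  s <- curve$s
  dens <- curve$density
  if (max(dens) <= min(dens) * (1 + 1e-12))
    warning("flat density curve; peak location is arbitrary")
  i <- which.max(dens)          # first maximum = smallest s on ties
  th <- p$thresholds
  bounds <- c(th$sh, th$sw, th$sstar, th$sfc, 1)
  k <- findInterval(s[i], bounds, left.open = TRUE, all.inside = TRUE)
  lo_b <- max(bounds[k], s[i] - diff(range(s)) / length(s) * 4)
  hi_b <- min(bounds[k + 1L], s[i] + diff(range(s)) / length(s) * 4)
  peak_s <- s[i]; peak_lp <- .log_ps_unnorm(s[i], dp, p)
  if (hi_b > lo_b) {
    opt <- optimize(function(x) .log_ps_unnorm(x, dp, p),
                    lower = lo_b, upper = hi_b, maximum = TRUE, tol = 1e-8)
    if (opt$objective > peak_lp ||
        (opt$objective == peak_lp && opt$maximum < peak_s)) {
      peak_s <- opt$maximum; peak_lp <- opt$objective
    }
  }
  # regime endpoints are candidate maxima the interior search cannot return
  for (b in bounds[-1]) {
    lpb <- .log_ps_unnorm(b, dp, p)
    if (lpb > peak_lp + 1e-12) { peak_s <- b; peak_lp <- lpb }
  }
  q <- .pdf_quantile(curve, probs)
  list(peak_s = peak_s, peak_value = exp(peak_lp + curve$log_c),
       lo = q[1L], hi = q[2L], broadness = q[2L] - q[1L])
}

#' @export
pdf_descriptors.sm_empirical_pdf <- function(curve, probs = c(0.05, 0.95)) {
  i <- which.max(curve$density)
  cum <- c(0, cumsum(curve$prob))
  cum <- cum / cum[length(cum)]
  edges <- curve$edges
  q <- approx(cum, edges, xout = probs, ties = "ordered")$y
  list(peak_s = curve$mids[i], peak_value = curve$density[i],
       lo = q[1L], hi = q[2L], broadness = q[2L] - q[1L])
}

# trapezoid CDF on the curve grid, normalized to end at exactly 1
.pdf_cdf_grid <- function(curve) {
  s <- curve$s
  d <- curve$density
  cdf <- c(0, cumsum((d[-1] + d[-length(d)]) / 2 * diff(s)))
  cdf / cdf[length(cdf)]
}

.pdf_quantile <- function(curve, probs) {
  cdf <- .pdf_cdf_grid(curve)
  approx(cdf, curve$s, xout = probs, ties = "ordered")$y
}

#' Cumulative distribution of an analytic density curve
#'
#' @param curve An `sm_pdf` object.
#' @param x Relative saturations at which to evaluate the CDF.
#' @return CDF values in `[0, 1]`.
#' @export
pdf_cdf <- function(curve, x) {
  stopifnot(inherits(curve, "sm_pdf"))
  cdf <- .pdf_cdf_grid(curve)
  out <- approx(curve$s, cdf, xout = x, ties = "ordered", rule = 2)$y
  out[x <= curve$s[1L]] <- 0
  out[x >= 1] <- 1
  out
}

#' Export a density curve
#'
#' `write_pdf_csv()` writes the `(s, density)` grid; `pdf_descriptor_list()`
#' returns the JSON-ready descriptor block.
#'
#' @param curve An `sm_pdf` object.
#' @param path Output CSV path.
#' @return `write_pdf_csv()` returns `path` invisibly.
#' @export
write_pdf_csv <- function(curve, path) {
  stopifnot(inherits(curve, "sm_pdf"))
  write.csv(data.frame(s = curve$s, density = curve$density), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_pdf_csv
#' @export
pdf_descriptor_list <- function(curve) {
  stopifnot(inherits(curve, "sm_pdf"))
  list(peak_s = curve$peak_s, peak_value = curve$peak_value,
       lo = unname(curve$interval_90[["lo"]]),
       hi = unname(curve$interval_90[["hi"]]),
       broadness = curve$broadness, c = curve$c)
}
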