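# Synthetic-data generators.  The pipeline's field inputs (daily station
# rainfall, TDR soil-moisture profiles) are emulated with the statistical
# structure the model itself assumes, so every downstream stage is testable
# without external downloads.

#' Generate a synthetic daily growing-season precipitation record
#'
#' Daily depths follow the marked-Poisson model thinned to daily
#' resolution: each season day is wet with probability `lam` and wet-day
#' depth is exponential with mean `alpha` (cm). An optional linear trend in
#' annual season totals is injected by scaling each year's depths so that
#' the expected totals follow `trend` mm per year around the multi-year
#' mean.
#'
#' @param years Number of growing seasons.
#' @param alpha Mean event depth (cm); default 0.765 (the mean daily depth
#'   0.371 cm divided by the wet-day frequency).
#' @param lam Wet-day frequency (1/day); default 0.485.
#' @param trend Injected trend in season totals (mm/a); default 0.
#' @param start_year First calendar year (default 2002).
#' @param season_start,season_end Season window as `"mm-dd"` (defaults
#'   May 1 - Sep 30).
#' @param seed Optional seed for reproducibility.
#' @return `data.frame` with `date` and `depth_mm` covering the season days
#'   of each year.
#' @export
generate_precipitation <- function(years = 10, alpha = 0.765, lam = 0.485,
                                   trend = 0, start_year = 2002,
                                   season_start = "05-01",
                                   season_end = "09-30", seed = NULL) {
  stopifnot(years >= 1, alpha > 0, lam >= 0, lam <= 1)
  if (!is.null(seed)) set.seed(seed)
  yrs <- seq.int(start_year, length.out = years)
  mid <- mean(yrs)
  out <- vector("list", years)
  for (k in seq_along(yrs)) {
    d0 <- as.Date(paste0(yrs[k], "-", season_start))
    d1 <- as.Date(paste0(yrs[k], "-", season_end))
    dates <- seq(d0, d1, by = "day")
    nd <- length(dates)
    depth_cm <- rbinom(nd, 1L, lam) * rexp(nd, rate = 1 / alpha)
    if (trend != 0) {
      expected_mm <- lam * alpha * 10 * nd
      fac <- max(0, 1 + trend * (yrs[k] - mid) / expected_mm)
      depth_cm <- depth_cm * fac
    }
    out[[k]] <- data.frame(date = dates, depth_mm = depth_cm * 10)
  }
  do.call(rbind, out)
}

#' Generate a synthetic layered soil-moisture record
#'
#' Simulates a root-zone saturation trajectory under the model and turns it
#' into per-layer volumetric water contents with depth-damped fluctuations
#' and Gaussian observation noise:
#' `theta_layer(t) = n * (s_mean + damping * (s(t) - s_mean)) + noise`,
#' clipped to `(0, n]`. Smaller damping at depth emulates the observed
#' decrease of moisture fluctuation amplitude with depth; the default noise
#' SD of 0.01 cm3/cm3 is a typical TDR probe accuracy.
#'
#' @param p An [model_params()] object used for the trajectory.
#' @param years Number of growing seasons (default 3).
#' @param depths Layer labels (cm); default `c(20, 40, 60, 80)`.
#' @param damping Per-layer fluctuation damping factors in `(0, 1]`;
#'   default `c(1, 0.8, 0.6, 0.5)`.
#' @param noise_sd Observation noise SD in theta units (default 0.01).
#' @param start_year First calendar year (default 2020).
#' @param season_start,season_end Season window (`"mm-dd"`).
#' @param burn_in Days of trajectory discarded before observations start
#'   (default 365).
#' @param seed Optional seed.
#' @return `data.frame` with `date`, `depth_cm`, `theta`, plus attribute
#'   `"s"`: the underlying daily root-zone saturation series.
#' @export
generate_moisture_observations <- function(p, years = 3,
                                           depths = c(20, 40, 60, 80),
                                           damping = c(1, 0.8, 0.6, 0.5),
                                           noise_sd = 0.01, start_year = 2020,
                                           season_start = "05-01",
                                           season_end = "09-30",
                                           burn_in = 365, seed = NULL) {
  stopifnot(inherits(p, "sm_params"), length(depths) == length(damping),
            all(damping > 0), all(damping <= 1), noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  yrs <- seq.int(start_year, length.out = years)
  dates <- do.call(c, lapply(yrs, function(y) {
    seq(as.Date(paste0(y, "-", season_start)),
        as.Date(paste0(y, "-", season_end)), by = "day")
  }))
  nd <- length(dates)
  traj <- simulate_soil_moisture(p, days = burn_in + nd)
  s <- traj$s[traj$day > burn_in]
  s_mean <- mean(s)
  n <- p$soil$n
  out <- vector("list", length(depths))
  for (k in seq_along(depths)) {
    theta <- n * (s_mean + damping[k] * (s - s_mean))
    if (noise_sd > 0) theta <- theta + rnorm(nd, sd = noise_sd)
    theta <- pmin(pmax(theta, 1e-6), n)
    out[[k]] <- data.frame(date = dates, depth_cm = depths[k], theta = theta)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$date, res$depth_cm), ]
  rownames(res) <- NULL
  attr(res, "s") <- s
  res
}
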