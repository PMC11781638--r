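#' Monte-Carlo simulation of daily soil-moisture dynamics
#'
#' Integrates the daily root-zone water balance as a jump process: each day
#' carries a Poisson number of storms (frequency `lam`) with exponential
#' depths (mean `alpha` cm), arriving at uniformly random times within the
#' day (rounded to the substep grid), which makes the arrival sequence an
#' exact Poisson process. The canopy intercepts up to `delta` cm per storm;
#' infiltration per storm is limited by available storage
#' `(1 - s) * n * Zr`, the excess leaving as saturation-excess runoff.
#' Between jumps, evapotranspiration and deep-percolation losses are
#' integrated by explicit Euler substeps of length `dt`.
#'
#' @param p An [model_params()] object.
#' @param days Number of simulated days (>= 1).
#' @param s0 Initial relative saturation in `(sh, 1]`; default field
#'   capacity.
#' @param seed Optional integer seed; runs with the same seed are
#'   bit-identical.
#' @param dt Loss-integration substep (days, default 0.01).
#' @param occupancy_binwidth Bin width of the time-occupancy histogram
#'   accumulated at substep resolution over `(sh, 1]` (default 0.01).
#' @return An object of class `sm_trajectory`: a `data.frame` with columns
#'   `day`, `s` and the per-day water ledger `rain_cm`, `interception_cm`,
#'   `infiltration_cm`, `runoff_cm`, `et_cm`, `leakage_cm` (all cm), with
#'   attributes `params`, `seed`, `dt`, `s0` and `occupancy` (a
#'   `data.frame` of bin edges and time-occupation density).
#' @export
#' @examples
#' traj <- simulate_soil_moisture(wanjia_params(), days = 400, seed = 1)
#' head(traj)
simulate_soil_moisture <- function(p, days, s0 = p$thresholds$sfc,
                                   seed = NULL, dt = 0.01,
                                   occupancy_binwidth = 0.01) {
  stopifnot(inherits(p, "sm_params"))
  if (!is.numeric(days) || length(days) != 1L || days < 1)
    stop("days must be a positive count")
  days <- as.integer(days)
  th <- p$thresholds
  if (!is.finite(s0) || s0 <= th$sh || s0 > 1)
    stop("initial saturation s0 must lie in (sh, 1]")
  if (!is.null(seed)) set.seed(seed)
  nbins <- as.integer(ceiling((1 - th$sh) / occupancy_binwidth))
  res <- sim_core(days, dt, p$soil$n, p$soil$Zr, th$sh, th$sw, th$sstar,
                  th$sfc, p$veg$Ew, p$veg$Emax, p$soil$Ks, p$soil$beta,
                  p$veg$delta, p$rain$alpha, p$rain$lam, s0,
                  th$sh, occupancy_binwidth, nbins)
  occ <- res$occupancy
  tot <- sum(occ)
  occ_df <- data.frame(
    lo = th$sh + occupancy_binwidth * (seq_len(nbins) - 1L),
    hi = th$sh + occupancy_binwidth * seq_len(nbins),
    density = if (tot > 0) occ / (tot * occupancy_binwidth) else occ
  )
  out <- data.frame(day = seq_len(days), s = res$s, rain_cm = res$rain_cm,
                    interception_cm = res$interception_cm,
                    infiltration_cm = res$infiltration_cm,
                    runoff_cm = res$runoff_cm, et_cm = res$et_cm,
                    leakage_cm = res$leakage_cm)
  structure(out, params = p, seed = seed, dt = dt, s0 = s0,
            occupancy = occ_df, class = c("sm_trajectory", "data.frame"))
}

#' Empirical stationary density from a trajectory
#'
#' Histogram estimator of the stationary density from the daily saturation
#' values after a burn-in period, with bin edges aligned to multiples of the
#' bin width.
#'
#' @param x An `sm_trajectory` or a numeric vector of saturations.
#' @param burn_in Days discarded from the start (trajectories only; default
#'   365).
#' @param binwidth Histogram bin width (default 0.01).
#' @return An object of class `sm_empirical_pdf`: list with `edges`, `mids`,
#'   `prob`, `density`, `n`, `burn_in`, `binwidth`. `sum(prob) == 1` and
#'   `sum(density) * binwidth == 1`.
#' @export
empirical_pdf <- function(x, burn_in = 365, binwidth = 0.01) {
  if (inherits(x, "sm_trajectory")) {
    if (burn_in >= nrow(x)) stop("burn_in must be smaller than the run length")
    s <- x$s[x$day > burn_in]
  } else {
    s <- as.numeric(x)
    burn_in <- 0
  }
  if (!length(s)) stop("no saturation values after burn-in")
  lo <- floor(min(s) / binwidth) * binwidth
  hi <- ceiling(max(s) / binwidth) * binwidth
  if (hi <= lo) hi <- lo + binwidth
  edges <- seq(lo, hi, by = binwidth)
  if (edges[length(edges)] < hi) edges <- c(edges, hi)
  counts <- tabulate(pmin(pmax(findInterval(s, edges, left.open = TRUE,
                                            all.inside = TRUE), 1L),
                          length(edges) - 1L),
                     nbins = length(edges) - 1L)
  prob <- counts / sum(counts)
  structure(list(edges = edges, mids = (edges[-1] + edges[-length(edges)]) / 2,
                 prob = prob, density = prob / binwidth, n = length(s),
                 burn_in = burn_in, binwidth = binwidth),
            class = "sm_empirical_pdf")
}

#' Runoff fraction of a trajectory
#'
#' Total saturation-excess runoff divided by total rainfall over the run.
#'
#' @param traj An `sm_trajectory`.
#' @return A fraction in `[0, 1]`, or `NA` if no rain fell.
#' @export
runoff_fraction <- function(traj) {
  stopifnot(inherits(traj, "sm_trajectory"))
  tot_rain <- sum(traj$rain_cm)
  if (tot_rain <= 0) return(NA_real_)
  sum(traj$runoff_cm) / tot_rain
}

#' Write a trajectory to CSV
#'
#' Writes the per-day ledger with the seed recorded in a `#` header comment.
#'
#' @param traj An `sm_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "sm_trajectory"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  seed <- attr(traj, "seed")
  writeLines(sprintf("# seed: %s; dt: %g; s0: %g",
                     if (is.null(seed)) "NA" else as.character(seed),
                     attr(traj, "dt"), attr(traj, "s0")), con)
  write.csv(as.data.frame(traj), con, row.names = FALSE)
  invisible(path)
}

#' Kolmogorov-Smirnov distance between a sample and an analytic curve
#'
#' Maximum absolute difference between the empirical CDF of the sampled
#' saturations and the analytic CDF, evaluated at the sample points.
#'
#' @param s Numeric vector of saturations (e.g. a trajectory's daily `s`).
#' @param curve An `sm_pdf` object.
#' @return The KS distance.
#' @export
ks_distance <- function(s, curve) {
  stopifnot(inherits(curve, "sm_pdf"))
  s <- sort(as.numeric(s))
  n <- length(s)
  cdf <- pdf_cdf(curve, s)
  max(pmax(abs(seq_len(n) / n - cdf), abs((seq_len(n) - 1L) / n - cdf)))
}
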