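#' Read a layered soil-moisture series
#'
#' Expects a CSV with columns `date`, `depth_cm` (layer label, e.g. 20, 40,
#' 60, 80) and `theta` (volumetric water content).
#'
#' @param path CSV path.
#' @return `data.frame` with `date` (`Date`), `depth_cm`, `theta`.
#' @export
read_moisture_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "depth_cm", "theta") %in% names(df)))
    stop("moisture CSV must have columns 'date', 'depth_cm' and 'theta'")
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("unparseable dates in moisture CSV")
  if (any(!is.finite(df$theta)) || any(df$theta <= 0) || any(df$theta >= 1))
    stop("theta must lie in (0, 1)")
  if (anyDuplicated(df[c("date", "depth_cm")]))
    stop("duplicate (date, depth) records")
  df[c("date", "depth_cm", "theta")]
}

#' Relative saturation from volumetric water content
#'
#' `s = theta / n`. Readings above porosity are rejected as supersaturated.
#'
#' @param theta Volumetric water content(s), `0 < theta <= n`.
#' @param n Soil porosity.
#' @return Relative saturation(s) in `(0, 1]`.
#' @export
relative_saturation <- function(theta, n) {
  if (!is.finite(n) || n <= 0 || n >= 1) stop("porosity n must lie in (0, 1)")
  if (any(!is.finite(theta)) || any(theta <= 0))
    stop("theta must be positive and finite")
  if (any(theta > n + 1e-12))
    stop("supersaturated reading: theta exceeds porosity n")
  pmin(theta / n, 1)
}

#' Depth-weighted root-zone average
#'
#' Thickness-weighted (area-weighted in the profile sense) mean water
#' content across layers. Layer labels are the lower boundaries of the
#' intervals defined by `layer_bounds`; for the default four equal 20-cm
#' layers over 0-80 cm each layer weighs 0.25. Dates missing any declared
#' layer yield `NA` (never imputed).
#'
#' @param series `data.frame` with `date`, `depth_cm`, `theta`.
#' @param layer_bounds Increasing depth boundaries (cm); default
#'   `c(0, 20, 40, 60, 80)`, labelling layers by their lower edge 20/40/60/80.
#' @return `data.frame` with `date` and `theta` (profile mean; `NA` where a
#'   layer is missing).
#' @export
root_zone_average <- function(series, layer_bounds = c(0, 20, 40, 60, 80)) {
  stopifnot(is.data.frame(series),
            all(c("date", "depth_cm", "theta") %in% names(series)))
  if (is.unsorted(layer_bounds, strictly = TRUE))
    stop("layer_bounds must be strictly increasing")
  labels <- layer_bounds[-1]
  thick <- diff(layer_bounds)
  w <- thick / sum(thick)
  dates <- sort(unique(series$date))
  theta <- vapply(dates, function(d) {
    sub <- series[series$date == d, ]
    th <- sub$theta[match(labels, sub$depth_cm)]
    if (anyNA(th)) NA_real_ else sum(w * th)
  }, numeric(1))
  data.frame(date = dates, theta = theta)
}

#' Descriptive statistics of a moisture series
#'
#' One row of max, min, mean, median, SD, CV, a Kolmogorov-Smirnov normality
#' p-value (against a normal with the estimated mean and SD), adjusted
#' Fisher-Pearson skewness and non-excess (Pearson) kurtosis.
#'
#' @param x Numeric series (volumetric content or saturation), `>= 8`
#'   observations.
#' @return A one-row `data.frame` with columns `n`, `max`, `min`, `mean`,
#'   `median`, `sd`, `cv`, `ks_p`, `skewness`, `kurtosis`. On a
#'   zero-variance series `cv`, `ks_p`, `skewness` and `kurtosis` are `NA`.
#' @export
moisture_summary_stats <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 8L) stop("need at least 8 observations")
  n <- length(x)
  m <- mean(x)
  sdev <- sd(x)
  if (sdev == 0) {
    warning("zero-variance series; CV, normality and shape statistics undefined")
    return(data.frame(n = n, max = max(x), min = min(x), mean = m,
                      median = median(x), sd = 0, cv = NA_real_,
                      ks_p = NA_real_, skewness = NA_real_,
                      kurtosis = NA_real_))
  }
  z <- x - m
  g1 <- mean(z^3) / (mean(z^2))^1.5
  skew <- g1 * sqrt(n * (n - 1)) / (n - 2)         # adjusted Fisher-Pearson
  kurt <- mean(z^4) / (mean(z^2))^2                # non-excess (Pearson)
  ks <- suppressWarnings(ks.test(x, "pnorm", mean = m, sd = sdev))
  data.frame(n = n, max = max(x), min = min(x), mean = m, median = median(x),
             sd = sdev, cv = sdev / m, ks_p = ks$p.value, skewness = skew,
             kurtosis = kurt)
}

#' Summary table for a layered moisture series
#'
#' Per-depth rows plus the root-zone average row, in the layout of a
#' growing-season soil-moisture characteristics table.
#'
#' @param series `data.frame` with `date`, `depth_cm`, `theta`.
#' @param layer_bounds Passed to [root_zone_average()].
#' @return `data.frame` with a `depth` column (layer label or e.g. `"0-80"`)
#'   followed by the [moisture_summary_stats()] columns.
#' @export
moisture_summary_table <- function(series, layer_bounds = c(0, 20, 40, 60, 80)) {
  labels <- layer_bounds[-1]
  rows <- lapply(labels, function(d) {
    cbind(depth = as.character(d),
          moisture_summary_stats(series$theta[series$depth_cm == d]))
  })
  rz <- root_zone_average(series, layer_bounds)
  rows <- c(rows, list(cbind(
    depth = paste0(layer_bounds[1], "-", layer_bounds[length(layer_bounds)]),
    moisture_summary_stats(rz$theta[!is.na(rz$theta)]))))
  do.call(rbind, rows)
}

#' Empirical probability distribution of relative saturation
#'
#' Per-bin probabilities and histogram density with bin edges aligned to
#' multiples of the bin width.
#'
#' @param s Relative saturations.
#' @param binwidth Bin width (default 0.01).
#' @return `data.frame` with `bin_lo`, `bin_mid`, `probability`, `density`;
#'   probabilities sum to 1 and `density = probability / binwidth`.
#' @export
empirical_distribution <- function(s, binwidth = 0.01) {
  s <- s[is.finite(s)]
  if (!length(s)) stop("empty saturation series")
  ep <- empirical_pdf(s, binwidth = binwidth)
  data.frame(bin_lo = ep$edges[-length(ep$edges)], bin_mid = ep$mids,
             probability = ep$prob, density = ep$density)
}
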