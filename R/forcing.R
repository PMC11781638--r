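#' Read a daily precipitation series
#'
#' Expects a CSV with columns `date` (ISO) and `depth_mm` (>= 0).
#'
#' @param path CSV path.
#' @return A `data.frame` with `date` (`Date`) and `depth_mm`.
#' @export
read_precip_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "depth_mm") %in% names(df)))
    stop("precipitation CSV must have columns 'date' and 'depth_mm'")
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("unparseable dates in precipitation CSV")
  if (any(!is.finite(df$depth_mm)) || any(df$depth_mm < 0))
    stop("depth_mm must be finite and >= 0")
  if (is.unsorted(df$date, strictly = TRUE))
    stop("dates must be strictly increasing")
  df[c("date", "depth_mm")]
}

# restrict a dated series to the growing-season window (month-day strings)
.in_season <- function(dates, season_start = "05-01", season_end = "09-30") {
  md <- format(dates, "%m-%d")
  md >= season_start & md <= season_end
}

#' Estimate rainfall-model parameters from a daily series
#'
#' Daily records are read as a thinned arrival process: the event frequency
#' `lam` is the wet-day fraction and the mean event depth `alpha` the mean
#' depth over wet days. The mean daily depth over all days (`alpha_daily`)
#' is reported alongside so that either reading of a tabulated "average
#' daily precipitation" can be fed to the model.
#'
#' @param series `data.frame` with `date`, `depth_mm`.
#' @param season_start,season_end Growing-season window as `"mm-dd"` strings
#'   (defaults May 1 - Sep 30); set either to `NULL` to use all days.
#' @return List with `alpha` (cm), `lam` (1/day), `alpha_daily` (cm),
#'   `n_days`, `n_wet`.
#' @export
estimate_rainfall_params <- function(series, season_start = "05-01",
                                     season_end = "09-30") {
  stopifnot(is.data.frame(series), all(c("date", "depth_mm") %in% names(series)))
  keep <- if (is.null(season_start) || is.null(season_end)) {
    rep(TRUE, nrow(series))
  } else {
    .in_season(series$date, season_start, season_end)
  }
  d <- series$depth_mm[keep]
  if (!length(d)) stop("season window selects no days")
  wet <- d > 0
  if (!any(wet)) stop("no wet days in the window; cannot estimate alpha")
  list(alpha = mean(d[wet]) / 10, lam = mean(wet),
       alpha_daily = mean(d) / 10, n_days = length(d), n_wet = sum(wet))
}

#' Storm depth-class statistics
#'
#' Fractions of wet days (event count) and of total depth falling in each
#' depth class, left-closed right-open on the class edges.
#'
#' @param series `data.frame` with `date`, `depth_mm`.
#' @param breaks_mm Class edges in mm; default `c(0, 5, 10, 15, Inf)`.
#' @param season_start,season_end Optional growing-season window (`NULL` =
#'   all days).
#' @return `data.frame` with `class`, `n`, `count_frac`, `depth_frac`; both
#'   fraction columns sum to 1.
#' @export
event_class_stats <- function(series, breaks_mm = c(0, 5, 10, 15, Inf),
                              season_start = NULL, season_end = NULL) {
  keep <- if (is.null(season_start) || is.null(season_end)) {
    rep(TRUE, nrow(series))
  } else {
    .in_season(series$date, season_start, season_end)
  }
  d <- series$depth_mm[keep]
  d <- d[d > 0]
  if (!length(d)) stop("no wet days; cannot classify events")
  cls <- cut(d, breaks_mm, right = FALSE, include.lowest = FALSE)
  cnt <- as.numeric(table(cls))
  dep <- as.numeric(tapply(d, cls, sum, default = 0))
  data.frame(class = levels(cls), n = cnt, count_frac = cnt / sum(cnt),
             depth_frac = dep / sum(dep))
}

#' Annual precipitation totals
#'
#' @param series `data.frame` with `date`, `depth_mm`.
#' @param season_start,season_end Optional window restricting each year to
#'   the growing season (`NULL` = whole year).
#' @return `data.frame` with `year`, `total_mm`.
#' @export
annual_totals <- function(series, season_start = NULL, season_end = NULL) {
  keep <- if (is.null(season_start) || is.null(season_end)) {
    rep(TRUE, nrow(series))
  } else {
    .in_season(series$date, season_start, season_end)
  }
  yr <- as.integer(format(series$date[keep], "%Y"))
  tot <- tapply(series$depth_mm[keep], yr, sum)
  data.frame(year = as.integer(names(tot)), total_mm = as.numeric(tot))
}

#' Linear trend of annual precipitation totals
#'
#' Ordinary least-squares slope of annual total against year, with the
#' two-sided t-test p-value on the slope.
#'
#' @param totals `data.frame` with `year` and `total_mm` (see
#'   [annual_totals()]).
#' @return List with `slope` (mm/a), `se`, `p_value`, `intercept`,
#'   `n_years`.
#' @export
precip_trend <- function(totals) {
  stopifnot(is.data.frame(totals), all(c("year", "total_mm") %in% names(totals)))
  if (nrow(totals) < 3L) stop("need at least 3 annual totals for a trend")
  fit <- lm(total_mm ~ year, data = totals)
  sm <- summary(fit)$coefficients
  list(slope = unname(coef(fit)[["year"]]), se = unname(sm["year", "Std. Error"]),
       p_value = unname(sm["year", "Pr(>|t|)"]),
       intercept = unname(coef(fit)[["(Intercept)"]]), n_years = nrow(totals))
}

#' Full precipitation-pattern summary
#'
#' Annual and growing-season totals with their linear trends, storm
#' depth-class statistics and rainfall-model parameter estimates, in one
#' JSON-ready list.
#'
#' @param series `data.frame` with `date`, `depth_mm`.
#' @param season_start,season_end Growing-season window (`"mm-dd"`).
#' @return A list of class `sm_precip_summary`.
#' @export
precip_summary <- function(series, season_start = "05-01",
                           season_end = "09-30") {
  ann <- annual_totals(series)
  gs <- annual_totals(series, season_start, season_end)
  structure(list(
    annual_totals = ann,
    season_totals = gs,
    annual_trend = if (nrow(ann) >= 3L) precip_trend(ann) else NULL,
    season_trend = if (nrow(gs) >= 3L) precip_trend(gs) else NULL,
    event_classes = event_class_stats(series, season_start = NULL,
                                      season_end = NULL),
    rainfall_params = estimate_rainfall_params(series, season_start, season_end)
  ), class = "sm_precip_summary")
}
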