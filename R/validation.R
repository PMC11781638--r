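#' Nash-Sutcliffe efficiency
#'
#' `NSE = 1 - sum((model - obs)^2) / sum((obs - mean(obs))^2)`. 1 is a
#' perfect match; 0 means the model is no better than the observed mean.
#'
#' @param model,obs Numeric vectors of equal length (>= 2) on a shared grid.
#' @return The NSE coefficient (`<= 1`).
#' @export
nse <- function(model, obs) {
  .check_pair(model, obs, min_len = 2L)
  denom <- sum((obs - mean(obs))^2)
  if (denom == 0) stop("observed values have zero variance; NSE undefined")
  1 - sum((model - obs)^2) / denom
}

#' Mean absolute error
#' @inheritParams nse
#' @return MAE (>= 0).
#' @export
mae <- function(model, obs) {
  .check_pair(model, obs, min_len = 1L)
  mean(abs(model - obs))
}

#' Root mean square error
#' @inheritParams nse
#' @return RMSE (>= MAE >= 0).
#' @export
rmse <- function(model, obs) {
  .check_pair(model, obs, min_len = 1L)
  sqrt(mean((model - obs)^2))
}

.check_pair <- function(model, obs, min_len) {
  if (length(model) != length(obs))
    stop("model and observed vectors must have equal length")
  if (length(obs) < min_len)
    stop("need at least ", min_len, " values")
  if (anyNA(model) || anyNA(obs)) stop("missing values not allowed")
  invisible(NULL)
}

#' Compare an analytic density with a measured empirical density
#'
#' Evaluates the analytic curve at the bin centers of the union of bins
#' where either density is positive, computes NSE, MAE and RMSE there, and
#' reports the peak/interval descriptors of both curves in the layout of a
#' simulated-vs-measured characteristics table.
#'
#' @param simulated An `sm_pdf` object (the model curve).
#' @param measured An `sm_empirical_pdf` object (e.g. from observed or
#'   simulated saturations).
#' @return An object of class `sm_pdf_comparison`: list with `table`
#'   (two rows: simulated and measured `max`/`min`/`peak`/`broadness`),
#'   `nse`, `mae`, `rmse`, `grid`, `model`, `obs`.
#' @export
compare_pdfs <- function(simulated, measured) {
  stopifnot(inherits(simulated, "sm_pdf"), inherits(measured, "sm_empirical_pdf"))
  sh <- simulated$params$thresholds$sh
  bw <- measured$binwidth
  # union support: bins with measured mass plus bins covering (sh, 1]
  lo <- min(measured$edges[1L], floor(sh / bw) * bw)
  hi <- max(measured$edges[length(measured$edges)], ceiling(1 / bw) * bw)
  edges <- seq(lo, hi, by = bw)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  obs <- numeric(length(mids))
  idx <- round((measured$mids - lo) / bw + 0.5)
  obs[idx] <- measured$density
  model <- numeric(length(mids))
  inside <- mids > sh & mids <= 1
  model[inside] <- exp(.log_ps_unnorm(mids[inside], simulated$derived,
                                      simulated$params) + simulated$log_c)
  keep <- obs > 0 | model > 0
  if (!any(obs > 0 & model > 0))
    stop("disjoint supports: measured and modeled densities do not overlap")
  ds <- pdf_descriptors(simulated)
  dm <- pdf_descriptors(measured)
  tab <- data.frame(
    value = c("simulated", "measured"),
    max = c(ds$hi, dm$hi), min = c(ds$lo, dm$lo),
    peak = c(ds$peak_value, dm$peak_value),
    peak_s = c(ds$peak_s, dm$peak_s),
    broadness = c(ds$broadness, dm$broadness)
  )
  structure(list(table = tab, nse = nse(model[keep], obs[keep]),
                 mae = mae(model[keep], obs[keep]),
                 rmse = rmse(model[keep], obs[keep]),
                 grid = mids[keep], model = model[keep], obs = obs[keep]),
            class = "sm_pdf_comparison")
}

#' @export
print.sm_pdf_comparison <- function(x, ...) {
  cat("Simulated vs measured soil-moisture density\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("NSE = %.3f  MAE = %.3f  RMSE = %.3f\n", x$nse, x$mae, x$rmse))
  invisible(x)
}
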