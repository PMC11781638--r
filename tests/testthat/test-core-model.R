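test_that("parameter constructors enforce their invariants", {
  expect_error(soil_params(n = 1.2, Zr = 80, Ks = 80, beta = 13.8), "porosity")
  expect_error(soil_params(n = 0.47, Zr = 80, Ks = 80, beta = 13.8, b = 5),
               "2\\*b")
  expect_silent(soil_params(n = 0.47, Zr = 80, Ks = 80, beta = 13.8, b = 4.9))
  expect_error(moisture_thresholds(0.3, 0.29, 0.71, 0.76), "sh < sw")
  expect_error(veg_params(Emax = 0.372, Ew = 0.5, delta = 0.15), "Ew")
  expect_error(rainfall_params(alpha = -1, lam = 0.485), "alpha")
})

test_that("derived parameters match direct evaluation of their definitions", {
  dp <- derive_params(table2(), compute_c = FALSE)
  nZr <- 0.47 * 80
  expect_equal(dp$lam_prime, 0.485 * exp(-0.15 / 0.371), tolerance = 1e-12)
  expect_equal(dp$lam_prime, 0.3238, tolerance = 5e-4)
  expect_equal(dp$gamma, nZr / 0.371, tolerance = 1e-12)
  expect_equal(dp$gamma, 101.35, tolerance = 1e-4)
  expect_equal(dp$eta, 0.372 / nZr)
  expect_equal(dp$eta_w, 0.186 / nZr)
  expect_equal(dp$m, 80 / (nZr * (exp(13.8 * 0.24) - 1)), tolerance = 1e-12)

  # zero interception passes every storm through: lam' = lam exactly
  p0 <- model_params(table2()$soil, table2()$thresholds,
                     veg_params(0.372, 0.186, 0), table2()$rain)
  expect_identical(derive_params(p0, compute_c = FALSE)$lam_prime, 0.485)

  # printed-variant convention exchanges the two normalized ET rates
  dps <- derive_params(wanjia_params(eta_convention = "as_printed"),
                       compute_c = FALSE)
  expect_equal(dps$eta, dp$eta_w)
  expect_equal(dps$eta_w, dp$eta)
})

test_that("evapotranspiration is piecewise linear and continuous", {
  p <- table2()
  expect_identical(evapotranspiration_rate(0.21, p), 0)     # hygroscopic point
  expect_identical(evapotranspiration_rate(0.1, p), 0)
  expect_equal(evapotranspiration_rate(0.29, p), 0.186)     # wilting point
  expect_equal(evapotranspiration_rate(0.50, p), (0.186 + 0.372) / 2)
  expect_equal(evapotranspiration_rate(0.71, p), 0.372)
  expect_identical(evapotranspiration_rate(1, p), 0.372)
  # continuity across all four boundaries
  for (b in c(0.21, 0.29, 0.71, 0.76)) {
    expect_equal(evapotranspiration_rate(b - 1e-9, p),
                 evapotranspiration_rate(b + 1e-9, p), tolerance = 1e-6)
  }
  expect_error(evapotranspiration_rate(1.2, p), "\\[0, 1\\]")
  expect_error(evapotranspiration_rate(-0.1, p), "\\[0, 1\\]")
})

test_that("leakage vanishes at field capacity, reaches Ks at saturation", {
  p <- table2()
  expect_identical(leakage_rate(0.76, p), 0)
  expect_equal(leakage_rate(1, p), 80)
  # independent scalar computation at s = 0.80
  expect_equal(leakage_rate(0.80, p),
               80 * (exp(13.8 * 0.04) - 1) / (exp(13.8 * 0.24) - 1),
               tolerance = 1e-12)
  s <- seq(0.76, 1, by = 1e-3)
  expect_true(all(diff(leakage_rate(s, p)) > 0))
})

test_that("total loss rate is zero below sh, nondecreasing, with the ET plateau", {
  p <- table2()
  expect_identical(total_loss_rate(c(0.05, 0.21), p), c(0, 0))
  expect_equal(total_loss_rate(0.71, p), 0.372 / (0.47 * 80), tolerance = 1e-12)
  s <- seq(0, 1, by = 1e-3)
  expect_true(all(diff(total_loss_rate(s, p)) >= 0))
})

test_that("closed-form density matches an independent product-form evaluation", {
  # oracle: the regime expressions written out directly as products of
  # powers, independent of the package's log-space evaluation
  p <- table2_unimodal()
  dp <- derive_params(p, compute_c = FALSE)
  eta <- dp$eta; etaw <- dp$eta_w; lamp <- dp$lam_prime; gam <- dp$gamma
  m <- dp$m; beta <- 13.8
  sh <- 0.21; sw <- 0.29; sstar <- 0.71; sfc <- 0.76

  s2 <- 0.45  # transpiration regime
  direct2 <- (1 / etaw) *
    (1 + (eta / etaw - 1) * (s2 - sw) / (sstar - sw))^(lamp * (sstar - sw) / (eta - etaw) - 1) *
    exp(-gam * s2)
  expect_equal(unnormalized_pdf(s2, dp, p), direct2, tolerance = 1e-12)

  s1 <- 0.25  # evaporation regime
  direct1 <- (1 / etaw) * ((s1 - sh) / (sw - sh))^(lamp * (sw - sh) / etaw - 1) *
    exp(-gam * s1)
  expect_equal(unnormalized_pdf(s1, dp, p), direct1, tolerance = 1e-12)

  s4 <- 0.9   # percolation regime
  direct4 <- (1 / eta) * exp(-(beta + gam) * s4 + beta * sfc) *
    (eta * exp(beta * s4) / ((eta - m) * exp(beta * sfc) + m * exp(beta * s4)))^(lamp / (beta * (eta - m)) + 1) *
    (eta / etaw)^(lamp * (sstar - sw) / (eta - etaw)) *
    exp(lamp / eta * (sfc - sstar))
  expect_equal(unnormalized_pdf(s4, dp, p), direct4, tolerance = 1e-10)

  expect_identical(unnormalized_pdf(c(0.1, 0.21), dp, p), c(0, 0))
})

test_that("density regimes join continuously and the curve normalizes", {
  set.seed(101)
  for (i in 1:20) {
    p <- random_valid_params()
    dp <- derive_params(p, compute_c = FALSE)
    th <- p$thresholds
    for (b in c(th$sw, th$sstar, th$sfc)) {
      lhs <- unnormalized_pdf(b, dp, p)
      rhs <- unnormalized_pdf(b + 1e-10, dp, p)
      expect_lt(abs(lhs - rhs) / lhs, 1e-6)
    }
    curve <- soil_moisture_pdf(p)
    expect_lt(abs(trapz(curve$s, curve$density) - 1), 1e-3)
    expect_true(all(curve$density >= 0))
    inner <- curve$s[curve$s > th$sh + 1e-6 & curve$s < 1]
    expect_true(all(is.finite(smstoch:::.log_ps_unnorm(inner, dp, p))))
  }
})

test_that("normalization constant scales linearly", {
  p <- table2()
  dp <- derive_params(p)
  s <- seq(0.3, 0.9, by = 1e-3)
  base <- trapz(s, dp$c * unnormalized_pdf(s, dp, p))
  doubled <- trapz(s, 2 * dp$c * unnormalized_pdf(s, dp, p))
  expect_equal(doubled, 2 * base, tolerance = 1e-12)
})

test_that("descriptors invert the CDF correctly on known shapes", {
  # symmetric triangle on [0, 1]: central interval symmetric about 0.5
  bw <- 0.005
  edges <- seq(0, 1, by = bw)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  dens <- 4 * pmin(mids, 1 - mids)
  prob <- dens * bw; prob <- prob / sum(prob)
  tri <- structure(list(edges = edges, mids = mids, prob = prob,
                        density = prob / bw, n = NA, burn_in = 0,
                        binwidth = bw),
                   class = "sm_empirical_pdf")
  d <- pdf_descriptors(tri)
  expect_lt(abs(d$peak_s - 0.5), bw)
  expect_equal(d$lo + d$hi, 1, tolerance = 1e-6)

  # uniform on (0.2, 0.8]: quantiles in closed form
  mids_u <- seq(0.2 + bw / 2, 0.8 - bw / 2, by = bw)
  pr <- rep(1 / length(mids_u), length(mids_u))
  uni <- structure(list(edges = seq(0.2, 0.8, by = bw), mids = mids_u,
                        prob = pr, density = pr / bw, n = NA, burn_in = 0,
                        binwidth = bw),
                   class = "sm_empirical_pdf")
  du <- pdf_descriptors(uni)
  expect_equal(du$lo, 0.2 + 0.05 * 0.6, tolerance = 1e-6)
  expect_equal(du$hi, 0.2 + 0.95 * 0.6, tolerance = 1e-6)
  expect_equal(du$broadness, 0.9 * 0.6, tolerance = 1e-6)
})

test_that("analytic descriptors are internally consistent", {
  curve <- soil_moisture_pdf(table2_unimodal())
  d <- pdf_descriptors(curve)
  expect_equal(d$broadness, d$hi - d$lo, tolerance = 1e-12)
  expect_true(d$lo < d$peak_s && d$peak_s < d$hi)
  # the peak is a true local maximum of the density
  eps <- 1e-4
  dp <- curve$derived
  expect_gte(unnormalized_pdf(d$peak_s, dp, curve$params),
             unnormalized_pdf(d$peak_s - eps, dp, curve$params))
  expect_gte(unnormalized_pdf(d$peak_s, dp, curve$params),
             unnormalized_pdf(d$peak_s + eps, dp, curve$params))
})

test_that("retention-curve interpolation recovers thresholds", {
  n <- 0.47
  # knots at the four target potentials pass through unchanged
  psi <- -c(10, 3, 1, 0.1, 0.03, 0.01)
  th <- n * c(0.20, 0.28, 0.40, 0.60, 0.71, 0.76)
  res <- thresholds_from_retention(psi, th, n)
  expect_equal(res$sh, 0.20, tolerance = 1e-12)
  expect_equal(res$sw, 0.28, tolerance = 1e-12)
  expect_equal(res$sstar, 0.71, tolerance = 1e-12)
  expect_equal(res$sfc, 0.76, tolerance = 1e-12)

  # log-linear interpolation: a target midway in log10|psi| between two
  # points returns the mean of the two water contents
  psi2 <- -c(30, 10 / 3, 0.09, 0.01)  # log-midpoints at 10 and 0.03 MPa
  th2 <- n * c(0.15, 0.30, 0.65, 0.85)
  res2 <- thresholds_from_retention(psi2, th2, n)
  expect_equal(res2$sh, (0.15 + 0.30) / 2, tolerance = 1e-9)
  expect_equal(res2$sstar, (0.65 + 0.85) / 2, tolerance = 1e-9)

  # smooth retention-like curve gives correctly ordered thresholds
  psi3 <- -10^seq(1.2, -2.2, length.out = 12)
  th3 <- n * (0.15 + 0.8 / (1 + (abs(psi3) / 0.05)^0.45))
  res3 <- thresholds_from_retention(psi3, th3, n)
  expect_true(res3$sh < res3$sw && res3$sw < res3$sstar && res3$sstar < res3$sfc)

  expect_error(thresholds_from_retention(-c(3, 1, 0.1, 0.01), n * c(.3, .4, .6, .76), n),
               "extrapolate")
  expect_error(thresholds_from_retention(psi, rev(th), n), "monotone")
})

test_that("model parameters round-trip through JSON and YAML", {
  p <- table2()
  for (ext in c(".json", ".yaml")) {
    f <- tempfile(fileext = ext)
    write_model_params(p, f)
    q <- read_model_params(f)
    expect_equal(q$soil$n, p$soil$n)
    expect_equal(q$thresholds$sfc, p$thresholds$sfc)
    expect_equal(q$rain$alpha, p$rain$alpha)
    expect_identical(q$eta_convention, "standard")
    unlink(f)
  }
})
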