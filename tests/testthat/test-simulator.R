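test_that("without rain the trajectory decays monotonically and stays above sh", {
  p <- model_params(table2()$soil, table2()$thresholds,
                    table2()$veg, rainfall_params(alpha = 0.371, lam = 1e-9))
  traj <- simulate_soil_moisture(p, days = 400, s0 = 0.9, seed = 1)
  expect_true(all(diff(traj$s) < 0))
  expect_true(all(traj$s > 0.21))
})

test_that("full interception reproduces the rain-free decay path", {
  dry <- model_params(table2()$soil, table2()$thresholds,
                      table2()$veg, rainfall_params(alpha = 0.371, lam = 1e-9))
  blocked <- model_params(table2()$soil, table2()$thresholds,
                          veg_params(0.372, 0.186, delta = 1e6),
                          rainfall_params(alpha = 0.371, lam = 0.485))
  t1 <- simulate_soil_moisture(dry, days = 500, s0 = 0.9, seed = 3)
  t2 <- simulate_soil_moisture(blocked, days = 500, s0 = 0.9, seed = 4)
  expect_equal(t1$s, t2$s, tolerance = 1e-12)
  expect_equal(sum(t2$infiltration_cm), 0)
  expect_equal(t2$interception_cm, t2$rain_cm)
})

test_that("the daily water ledger closes to machine precision", {
  for (seed in c(11, 12)) {
    p <- table2()
    traj <- simulate_soil_moisture(p, days = 3000, seed = seed)
    nZr <- p$soil$n * p$soil$Zr
    ds <- diff(c(attr(traj, "s0"), traj$s))
    resid <- nZr * ds -
      (traj$infiltration_cm - traj$et_cm - traj$leakage_cm)
    expect_lt(max(abs(resid)), 1e-6)
    # infiltration never exceeds throughfall
    expect_true(all(traj$infiltration_cm <=
                      traj$rain_cm - traj$interception_cm + 1e-12))
    expect_true(all(traj$runoff_cm >= 0))
  }
})

test_that("runs are reproducible under a seed and differ across seeds", {
  p <- table2()
  a <- simulate_soil_moisture(p, days = 400, seed = 99)
  b <- simulate_soil_moisture(p, days = 400, seed = 99)
  expect_identical(a$s, b$s)
  expect_identical(a$rain_cm, b$rain_cm)
  c <- simulate_soil_moisture(p, days = 400, seed = 100)
  expect_false(identical(a$s, c$s))
})

test_that("empirical pdf handles degenerate and two-bin samples", {
  one <- empirical_pdf(rep(0.415, 100), binwidth = 0.01)
  expect_equal(length(one$prob), 1L)
  expect_equal(one$prob, 1)
  expect_equal(one$density, 100)

  two <- empirical_pdf(c(rep(0.405, 50), rep(0.415, 50)), binwidth = 0.01)
  expect_equal(two$prob, c(0.5, 0.5))
  expect_equal(two$density, c(50, 50))
  expect_equal(sum(two$density) * two$binwidth, 1, tolerance = 1e-9)

  traj <- simulate_soil_moisture(table2(), days = 1000, seed = 5)
  expect_error(empirical_pdf(traj, burn_in = 1000), "burn_in")
})

test_that("long-run empirical mean matches the analytic mean", {
  p <- table2()
  traj <- simulate_soil_moisture(p, days = 1e5, seed = 21)
  curve <- soil_moisture_pdf(p)
  analytic_mean <- trapz(curve$s, curve$s * curve$density)
  ep <- empirical_pdf(traj)
  emp_mean <- sum(ep$mids * ep$prob)
  expect_lt(abs(emp_mean - analytic_mean), 0.01)
})

test_that("runoff fraction is a proper fraction and NA without rain", {
  dry <- model_params(table2()$soil, table2()$thresholds,
                      table2()$veg, rainfall_params(alpha = 0.371, lam = 1e-9))
  t0 <- simulate_soil_moisture(dry, days = 200, seed = 7)
  expect_true(is.na(runoff_fraction(t0)))

  t1 <- simulate_soil_moisture(table2(), days = 5000, seed = 8)
  f1 <- runoff_fraction(t1)
  expect_true(f1 >= 0 && f1 <= 1)

  # shallow storage, weak drainage, heavy storms: runoff dominates
  heavy <- model_params(
    soil_params(n = 0.3, Zr = 20, Ks = 0.05, beta = 12),
    moisture_thresholds(0.1, 0.15, 0.4, 0.6),
    veg_params(Emax = 0.2, Ew = 0.02, delta = 0),
    rainfall_params(alpha = 5, lam = 0.9))
  t2 <- simulate_soil_moisture(heavy, days = 3000, seed = 9)
  expect_gt(runoff_fraction(t2), 0.5)
})

test_that("halving the loss substep leaves the stationary mean unchanged", {
  p <- table2()
  m1 <- mean(simulate_soil_moisture(p, days = 5e4, seed = 31, dt = 0.01)$s)
  m2 <- mean(simulate_soil_moisture(p, days = 5e4, seed = 31, dt = 0.005)$s)
  expect_lt(abs(m1 - m2), 0.002)
})

test_that("trajectory CSV export records the seed and round-trips", {
  traj <- simulate_soil_moisture(table2(), days = 50, seed = 17)
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, f)
  header <- readLines(f, n = 1)
  expect_match(header, "seed: 17")
  back <- read.csv(f, comment.char = "#")
  expect_equal(back$s, traj$s)
  unlink(f)
})
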