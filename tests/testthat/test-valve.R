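vp_test <- valve_params(a_max = 1.852)

test_that("opening-fraction rate law saturates at the bounds and follows dp", {
  expect_equal(valve_rate(1, 10, vp_test), 0)
  expect_equal(valve_rate(0, -10, vp_test), 0)
  th <- c(0.2, 0.5, 0.9)
  expect_true(all(valve_rate(th, 5, vp_test) > 0))
  expect_true(all(valve_rate(th, -5, vp_test) < 0))
  expect_equal(valve_rate(0.5, 0, vp_test), 0)
})

test_that("theta stays in [0, 1] under arbitrary pressure forcing", {
  set.seed(3)
  # random smooth pressure forcing, amplitude far beyond physiological
  co <- stats::rnorm(6, sd = 80)
  dp_fun <- function(t) {
    co[1] + co[2] * sin(2 * pi * t) + co[3] * cos(4 * pi * t) +
      co[4] * sin(6 * pi * t) + co[5] * cos(10 * pi * t) + co[6]
  }
  rhs <- function(t, y, p) {
    r <- valve_rate(y[1], dp_fun(t), vp_test)
    if (y[1] >= 1 && r > 0) r <- 0
    if (y[1] <= 0 && r < 0) r <- 0
    list(r)
  }
  sol <- deSolve::ode(c(theta = 0.5), seq(0, 3, by = 1e-3), rhs, NULL)
  expect_true(all(sol[, "theta"] >= -1e-9 & sol[, "theta"] <= 1 + 1e-9))
})

test_that("effective area interpolates linearly between leak and full opening", {
  expect_equal(effective_area(0, vp_test), vp_test$a_leak)
  expect_equal(effective_area(1, vp_test), vp_test$a_max)
  expect_equal(effective_area(0.5, vp_test),
               (vp_test$a_leak + vp_test$a_max) / 2)
})

test_that("Bernoulli orifice law reproduces printed peak arithmetic and scalings", {
  saline <- fluid_properties()
  expect_equal(valve_pressure_flow(0, 0, 1, saline, vp_test), 0)
  # peak porcine operating point: 452.5 mL/s through 1.852 cm^2 ~ 22.4 mmHg
  dp <- valve_pressure_flow(452.5, 0, 1, saline, vp_test)
  expect_equal(dp, 22.4, tolerance = 0.002)
  # doubling the area quarters the quadratic term
  vp2 <- valve_params(a_max = 2 * 1.852)
  expect_equal(valve_pressure_flow(452.5, 0, 1, saline, vp2), dp / 4,
               tolerance = 1e-9)
})

test_that("EOA calibration inverts the orifice law and is monotone", {
  saline <- fluid_properties()
  expect_equal(calibrate_eoa(452.5, 22.4), 1.85, tolerance = 0.001)
  expect_equal(calibrate_eoa(425.1, 16.4), 2.03, tolerance = 0.002)
  # round trip: the calibrated area reproduces the calibrating gradient
  eoa <- calibrate_eoa(452.5, 22.4)
  vp <- valve_params(a_max = eoa)
  expect_equal(valve_pressure_flow(452.5, 0, 1, saline, vp), 22.4,
               tolerance = 1e-9)
  dps <- c(5, 10, 20, 40, 80)
  expect_true(all(diff(calibrate_eoa(452.5, dps)) < 0))
})

test_that("diastolic membrane state solves the Laplace balance", {
  vp <- valve_preset("porcine")
  at_rest <- diastolic_membrane_state(vp, 0)
  expect_equal(at_rest$lambda, 1)
  expect_equal(at_rest$tension, 0)

  # stretch is strictly increasing with the diastolic load
  lams <- vapply(c(20, 50, 100, 150),
                 function(dp) diastolic_membrane_state(vp, dp)$lambda,
                 numeric(1))
  expect_true(all(diff(lams) > 0))

  # fine-grid scan oracle at 100 mmHg
  ms <- diastolic_membrane_state(vp, 100)
  target <- 100 * KPA_PER_MMHG * vp$cap_radius / 2
  grid <- seq(1.0001, 1.6, length.out = 40001)
  tens <- vapply(grid, function(l) {
    vp$thickness * plane_stress_biaxial(vp$material, l, l)[["sigma11"]]
  }, numeric(1))
  lam_scan <- grid[which.min(abs(tens - target))]
  expect_equal(ms$lambda, lam_scan, tolerance = 1e-4)
  expect_gt(ms$von_mises, 0)

  # stiff-bracket failure names the search range
  expect_error(diastolic_membrane_state(vp, 1e7, lambda_max = 1.05),
               "1.05")
})

test_that("PDVA proxy is proportional to the opening fraction", {
  th <- rep(0, 10)
  expect_equal(pdva_proxy(th, vp_test), rep(0, 10))
  expect_equal(pdva_proxy(rep(1, 5), vp_test), rep(vp_test$a_proj_max, 5))
  t1 <- seq(0, 1, 0.1)
  t2 <- pmin(t1 + 0.2, 1)
  expect_true(all(pdva_proxy(t2, vp_test) >= pdva_proxy(t1, vp_test)))
})

test_that("valve opening follows the pressure crossing and closure follows flow reversal", {
  run <- porcine_calibration()$run
  tt <- run$time
  s <- run$signals
  dp <- s$p_lv_mmHg - s$p_ao_mmHg
  i_cross <- which(dp > 0 & c(FALSE, dp[-length(dp)] <= 0))[1]
  i_open <- which(s$theta > 0.02)[1]
  # opening begins at the pressure crossing (within a few ms)
  expect_lt(abs(tt[i_open] - tt[i_cross]), 0.01)
  # closure completes only after flow reversal
  i_rev <- which(s$q_ao_mL_s < 0 & seq_along(tt) > i_open)[1]
  i_closed <- which(s$theta < 0.01 & seq_along(tt) > i_open)[1]
  expect_gt(tt[i_closed], tt[i_rev])
})

test_that("a fully competent closed valve carries no diastolic flow", {
  circ <- circuit_preset("porcine")
  circ$valve$a_leak <- 0
  run <- run_to_periodic(circ, tol = 1e-3, max_cycles = 30)
  shut <- run$signals$theta < 1e-3 & run$time > 0.6
  expect_true(any(shut))
  expect_lt(max(abs(run$signals$q_ao_mL_s[shut])), 0.05)
})
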