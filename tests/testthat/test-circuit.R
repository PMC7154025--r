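test_that("diode flow is a smooth one-way law", {
  # reverse bias: effectively closed
  expect_lt(diode_flow(0, 10, 0.028), 0.01 / 0.028)
  # forward: printed mitral resistance passes ~100 mL/s at 2.8 mmHg
  expect_equal(diode_flow(2.8, 0, 0.028), 100, tolerance = 1e-6)
  # continuity and monotonicity across the smoothing region
  dp <- seq(-0.2, 0.2, by = 1e-3)
  q <- diode_flow(dp, 0, 0.028)
  expect_true(all(diff(q) >= 0))
  expect_lt(max(abs(diff(q))), 0.06)
})

test_that("R-C-R outlet satisfies its closed forms", {
  wk <- rcr_windkessel(r_c = 0.0218, r_p = 1.31, c = 0.915)
  # steady flow: equilibrium inlet pressure Q0 (Rc + Rp)
  q0 <- 100
  eq <- rcr_outlet_update(wk, q0, p_store = q0 * wk$r_p)
  expect_equal(eq$dp_store_dt, 0)
  expect_equal(eq$p_inlet, q0 * (wk$r_c + wk$r_p))
  # zero inflow: pure exponential decay with the printed time constant
  tau <- wk$r_p * wk$c
  expect_equal(tau, 1.19865, tolerance = 1e-12)
  p0 <- 80
  for (t in c(0, 0.3, 1)) {
    p <- p0 * exp(-t / tau)
    expect_equal(rcr_outlet_update(wk, 0, p)$dp_store_dt, -p / tau,
                 tolerance = 1e-12)
  }
})

test_that("the circuit is at rest when all sources and states are zero", {
  cfg <- circuit_preset("porcine")
  cfg$driver <- list(base = 0, amp = 0, width = 0.26)
  state <- stats::setNames(rep(0, 5), c("p_via", "p_lv", "p_sto",
                                        "theta", "q"))
  d <- assemble_rhs(cfg, state, 0)
  expect_equal(unname(d), rep(0, 5))
  # non-finite states are an integration failure with a time stamp
  state[1] <- NaN
  expect_error(assemble_rhs(cfg, state, 0.25), "0.25")
})

test_that("linear-valve periodic solution matches the frequency-domain oracle", {
  vp <- valve_params(a_max = 2, law = "linear", r_linear = 0.1)
  circ <- circuit_preset("porcine", valve = vp)
  circ$driver <- list(base = 8, amp = 120, width = 0.3, shape = 1)
  run <- run_to_periodic(circ, tol = 1e-6, max_cycles = 40)
  expect_true(run$converged)

  # independent complex nodal analysis per harmonic of the driver
  up <- circ$upstream
  wk <- circ$downstream
  clv <- circ$c_lv
  rl <- vp$r_linear + wk$r_c
  A <- rbind(
    c(-(1 / up$r1 + 1 / up$r2) / up$c_via, 1 / (up$r2 * up$c_via), 0),
    c(1 / (up$r2 * clv), -(1 / up$r2 + 1 / rl) / clv, 1 / (rl * clv)),
    c(0, 1 / (rl * wk$c), -(1 / rl + 1 / wk$r_p) / wk$c))
  tt <- run$time
  n <- length(tt)
  ph <- tt %% run$period
  pp <- 8 + 120 * ifelse(ph < 0.3, sin(pi * ph / 0.3)^2, 0)
  B <- stats::fft(pp) / n
  om <- 2i * pi * c(0:(n %/% 2), -(ceiling(n / 2) - 1):-1) / run$period
  X <- matrix(0 + 0i, 3, n)
  for (k in seq_len(n)) {
    X[, k] <- solve(diag(3) * om[k] - A,
                    c(B[k] / (up$r1 * up$c_via), 0, 0))
  }
  xt <- t(Re(sapply(1:3, function(i) stats::fft(X[i, ], inverse = TRUE))))
  states <- run$states[, c("p_via", "p_lv", "p_sto")]
  for (i in 1:3) {
    rel <- sqrt(mean((states[, i] - xt[i, ])^2)) / sqrt(mean(xt[i, ]^2))
    expect_lt(rel, 0.005)
  }
})

test_that("periodic convergence is fast for the linear system and the grid is uniform 1 kHz", {
  vp <- valve_params(a_max = 2, law = "linear", r_linear = 0.1)
  circ <- circuit_preset("porcine", valve = vp)
  circ$driver <- list(base = 8, amp = 120, width = 0.3)
  run <- run_to_periodic(circ, tol = 1e-3, max_cycles = 10)
  expect_true(run$converged)
  expect_lte(run$cycles_run, 10)
  dt <- diff(run$time)
  expect_equal(dt, rep(1e-3, length(dt)), tolerance = 1e-12)
  expect_equal(run$time[1], 0)
  # last sample of the half-open 1 kHz grid below T = 60/70 s
  expect_equal(max(run$time), floor((60 / 70) / 1e-3) * 1e-3,
               tolerance = 1e-9)
})

test_that("halving the integrator step leaves the converged cycle unchanged to 0.1%", {
  circ <- circuit_preset("porcine")
  r1 <- run_to_periodic(circ, tol = 1e-5, hmax = 1e-3)
  r2 <- run_to_periodic(circ, tol = 1e-5, hmax = 5e-4,
                        init = r1$final_state)
  num <- sqrt(mean((r1$signals$q_ao_mL_s - r2$signals$q_ao_mL_s)^2))
  den <- sqrt(mean(r2$signals$q_ao_mL_s^2))
  expect_lt(num / den, 1e-3)
})

test_that("resistive elements dissipate and diastolic aortic decay matches Rp*C", {
  cal <- porcine_calibration()
  run <- cal$run
  tt <- run$time
  s <- run$signals
  # net energy into the valve over the periodic cycle is dissipated
  diss <- pracma::trapz(tt, (s$p_lv_mmHg - s$p_ao_mmHg) * s$q_ao_mL_s)
  expect_gt(diss, 0)
  # late-diastolic aortic pressure decays with the downstream Rp*C constant
  idx <- which(tt > 0.63 & tt < 0.85)
  fitc <- stats::coef(stats::lm(log(s$p_ao_mmHg[idx]) ~ tt[idx]))
  tau_hat <- -1 / fitc[[2]]
  expect_equal(tau_hat, 1.19865, tolerance = 0.05)
})

test_that("zero-phase low-pass filter has unit DC gain and attenuates above cutoff", {
  fs <- 1000
  t <- seq(0, 1, by = 1 / fs)
  expect_equal(lowpass_filter(rep(3, 500), fs = fs), rep(3, 500),
               tolerance = 1e-8)
  x200 <- sin(2 * pi * 200 * t)
  y <- lowpass_filter(x200, fs = fs, fc = 100)
  mid <- 300:700
  atten <- 20 * log10(max(abs(y[mid])) / 1)
  expect_lt(atten, -20)
  # linearity
  a <- sin(2 * pi * 5 * t)
  b <- 0.5 * cos(2 * pi * 20 * t)
  expect_equal(lowpass_filter(a + b, fs = fs),
               lowpass_filter(a, fs = fs) + lowpass_filter(b, fs = fs),
               tolerance = 1e-10)
  expect_error(lowpass_filter(a, fs = 150, fc = 100), "coarse")
})
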