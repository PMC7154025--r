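#' Test-fluid properties
#'
#' @param rho Density (g/cm^3), > 0.
#' @param mu Dynamic viscosity (cP), > 0. Saline at 25 C is the default;
#'   `fluid_properties(1.0, 3.5)` gives the Newtonian blood-analogue preset.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(rho = 1.0, mu = 1.0) {
  stopifnot(rho > 0, mu > 0)
  structure(list(rho = rho, mu = mu), class = "fluid_properties")
}

#' Three-element Windkessel (R-C-R) load
#'
#' Characteristic resistance in series with a parallel compliance/peripheral
#' resistance pair. Compliance values are in mL/mmHg (physiological
#' convention; printed magnitudes are interpreted on this scale).
#'
#' @param r_c Characteristic resistance (mmHg s/mL), > 0.
#' @param r_p Peripheral resistance (mmHg s/mL), > 0.
#' @param c Compliance (mL/mmHg), > 0.
#' @return An object of class `rcr_windkessel`.
#' @export
rcr_windkessel <- function(r_c, r_p, c) {
  stopifnot(r_c > 0, r_p > 0, c > 0)
  structure(list(r_c = r_c, r_p = r_p, c = c), class = "rcr_windkessel")
}

#' Smooth one-way (diode) valve flow
#'
#' Flow through an ideal diode with series resistance `r`, with C-infinity
#' softplus smoothing of width `eps_smooth` around zero pressure difference:
#' q ~= max(p_up - p_down, 0) / r.
#'
#' @param p_up,p_down Upstream/downstream pressures (mmHg).
#' @param r Open-diode resistance (mmHg s/mL), > 0.
#' @param eps_smooth Smoothing width (mmHg), > 0.
#' @return Flow (mL/s); vectorized, continuous and non-decreasing in
#'   `p_up - p_down`.
#' @export
diode_flow <- function(p_up, p_down, r, eps_smooth = 0.01) {
  stopifnot(r > 0, eps_smooth > 0)
  dp <- p_up - p_down
  x <- dp / eps_smooth
  ifelse(x > 30, dp / r, eps_smooth * log1p(exp(pmin(x, 30))) / r)
}

#' One step of the R-C-R outlet relation
#'
#' Given the instantaneous inflow, returns the inlet pressure seen by the
#' upstream system and the rate of change of the stored (compliance-node)
#' pressure: p_inlet = q_in r_c + p_store and
#' c dp_store/dt = q_in - p_store / r_p.
#'
#' @param wk An [rcr_windkessel()] object.
#' @param q_in Inflow (mL/s).
#' @param p_store Stored pressure state (mmHg).
#' @return List with `p_inlet` (mmHg) and `dp_store_dt` (mmHg/s).
#' @export
rcr_outlet_update <- function(wk, q_in, p_store) {
  stopifnot(inherits(wk, "rcr_windkessel"))
  list(p_inlet = q_in * wk$r_c + p_store,
       dp_store_dt = (q_in - p_store / wk$r_p) / wk$c)
}

# Smooth periodic systolic pulse of width `width` starting at phase 0 and
# zero elsewhere in the cycle: (sin^2)^shape with unit peak amplitude.
# shape = 1 is a hann pulse; shape < 1 flattens the top (piston-like pumps
# eject flatter pulses), shape > 1 sharpens it.
systolic_hump <- function(t, period, width, shape = 1) {
  ph <- t %% period
  ifelse(ph < width, sin(pi * ph / width)^2, 0)^shape
}

# Mean of the unit-amplitude pulse over its width: integral_0^1 sin(pi u)^(2p)
# du, used for pulse volume bookkeeping.
hump_mean <- function(shape) {
  gamma(shape + 0.5) / (sqrt(pi) * gamma(shape + 1))
}

#' Pulse-duplicator circuit configuration
#'
#' Assembles the reduced-order driving/loading description coupled to the
#' valve surrogate. Two topologies are supported, mirroring the two
#' experimental platforms:
#'
#' * `"porcine"`: pressure source -> R1 -> VIA node (C_VIA to ground) ->
#'   R2 -> ventricular node (small regularizing compliance `c_lv`) ->
#'   valve surrogate -> aortic node -> downstream R-C-R -> ground.
#' * `"pericardial"`: flow source into node V1 (C_VIA1); V1 -> R_VIA -> node
#'   V2 (C_VIA2) which is the ventricular node; atrial pressure source ->
#'   mitral diode (R_MV) -> V2; R_out returns from V1 (default) or V2 to
#'   ground; valve surrogate -> aortic node -> downstream R-C-R -> ground.
#'
#' Ground/reservoir pressure is 0 mmHg. All topology choices are carried in
#' the configuration so alternatives are testable.
#'
#' @param topology `"porcine"` or `"pericardial"`.
#' @param upstream Named list of upstream parameters. Porcine: `r1`, `r2`,
#'   `c_via`. Pericardial: `c_via1`, `c_via2`, `r_via`, `r_out`, `r_mv`,
#'   optionally `r_out_node` (`"v1"` or `"v2"`).
#' @param downstream An [rcr_windkessel()] object.
#' @param valve A [valve_params()] object.
#' @param fluid A [fluid_properties()] object.
#' @param driver Named list describing the pump source. Porcine (pressure
#'   source, mmHg): `base`, `amp`, `width`. Pericardial (flow source, mL/s):
#'   `amp`, `width`, `p_la` (mmHg), and optionally `refill_gap` (s).
#' @param hr_bpm Pulse rate (beats per minute).
#' @param c_lv Small regularizing ventricular compliance for the porcine
#'   topology (mL/mmHg).
#' @return An object of class `circuit_config`.
#' @export
circuit_config <- function(topology = c("porcine", "pericardial"),
                           upstream, downstream, valve,
                           fluid = fluid_properties(),
                           driver, hr_bpm = 70, c_lv = 0.02) {
  topology <- match.arg(topology)
  stopifnot(inherits(downstream, "rcr_windkessel"),
            inherits(valve, "valve_params"),
            inherits(fluid, "fluid_properties"),
            is.list(upstream), is.list(driver), hr_bpm > 0, c_lv > 0)
  need <- if (topology == "porcine") {
    c("r1", "r2", "c_via")
  } else {
    c("c_via1", "c_via2", "r_via", "r_out", "r_mv")
  }
  miss <- setdiff(need, names(upstream))
  if (length(miss)) {
    stop("upstream parameters missing for ", topology, " topology: ",
         paste(miss, collapse = ", "))
  }
  stopifnot(all(unlist(upstream[need]) > 0))
  if (topology == "pericardial" && is.null(upstream$r_out_node)) {
    upstream$r_out_node <- "v1"
  }
  structure(list(
    topology = topology, upstream = upstream, downstream = downstream,
    valve = valve, fluid = fluid, driver = driver,
    hr_bpm = hr_bpm, period = 60 / hr_bpm, c_lv = c_lv
  ), class = "circuit_config")
}

# State vector layout for each topology (bernoulli law):
#   porcine:     p_via, p_lv, p_sto, theta, q
#   pericardial: p_v1,  p_lv, p_sto, theta, q
# With the linear valve law the flow is algebraic and theta/q are dropped.
state_names <- function(config) {
  first <- if (config$topology == "porcine") "p_via" else "p_v1"
  if (config$valve$law == "linear") {
    c(first, "p_lv", "p_sto")
  } else {
    c(first, "p_lv", "p_sto", "theta", "q")
  }
}

initial_state <- function(config) {
  s <- c(10, 10, 80, 0, 0)[seq_along(state_names(config))]
  stats::setNames(s, state_names(config))
}

# Driver source value at time t (pressure for porcine, flow for pericardial).
driver_value <- function(config, t) {
  d <- config$driver
  T <- config$period
  shape <- if (is.null(d$shape)) 1 else d$shape
  if (config$topology == "porcine") {
    d$base + d$amp * systolic_hump(t, T, d$width, shape)
  } else {
    # zero-net-volume piston: systolic ejection plus diastolic refill
    gap <- if (is.null(d$refill_gap)) 0.1 * (T - d$width) else d$refill_gap
    w_d <- T - d$width - 2 * gap
    amp_d <- d$amp * d$width * hump_mean(shape) / (w_d * 0.5)
    ph <- t %% T
    eject <- d$amp * systolic_hump(ph, T, d$width, shape)
    refill <- ifelse(ph > d$width + gap & ph < d$width + gap + w_d,
                     -amp_d * sin(pi * (ph - d$width - gap) / w_d)^2, 0)
    eject + refill
  }
}

#' Time derivative of the circuit state
#'
#' Assembles d(state)/dt for the configured topology at time `t`, enforcing
#' volume (charge) balance at every compliance node. Used as the right-hand
#' side of the ODE integration in [run_to_periodic()] and exported for
#' direct inspection and testing.
#'
#' @param config A [circuit_config()] object.
#' @param state Named numeric state vector (see Details of
#'   [circuit_config()]); pressures in mmHg, flow in mL/s.
#' @param t Time (s).
#' @return Named numeric vector of time derivatives.
#' @export
assemble_rhs <- function(config, state, t) {
  if (any(!is.finite(state))) {
    stop(sprintf("integration failure: non-finite state at t = %.6f s", t))
  }
  up <- config$upstream
  wk <- config$downstream
  vp <- config$valve
  linear <- vp$law == "linear"

  p_lv <- state[["p_lv"]]
  p_sto <- state[["p_sto"]]

  if (linear) {
    # algebraic valve flow through r_linear in series with r_c
    q <- (p_lv - p_sto) / (vp$r_linear + wk$r_c)
  } else {
    theta <- state[["theta"]]
    q <- state[["q"]]
  }
  out <- rcr_outlet_update(wk, q, p_sto)
  p_ao <- out$p_inlet
  dp_valve <- p_lv - p_ao

  if (config$topology == "porcine") {
    p_via <- state[["p_via"]]
    p_pump <- driver_value(config, t)
    q1 <- (p_pump - p_via) / up$r1
    q2 <- (p_via - p_lv) / up$r2
    d_first <- (q1 - q2) / up$c_via
    q_in_lv <- q2
  } else {
    p_v1 <- state[["p_v1"]]
    q_pump <- driver_value(config, t)
    q_via <- (p_v1 - p_lv) / up$r_via
    q_out <- if (up$r_out_node == "v1") p_v1 / up$r_out else p_lv / up$r_out
    q_mv <- diode_flow(config$driver$p_la, p_lv, up$r_mv)
    d_first <- (q_pump - q_via -
                  (if (up$r_out_node == "v1") q_out else 0)) / up$c_via1
    q_in_lv <- q_via + q_mv - (if (up$r_out_node == "v2") q_out else 0)
  }

  c_lv <- if (config$topology == "porcine") config$c_lv else up$c_via2
  d_p_lv <- (q_in_lv - q) / c_lv
  d_p_sto <- out$dp_store_dt

  if (linear) {
    return(stats::setNames(c(d_first, d_p_lv, d_p_sto), state_names(config)))
  }
  # floor keeps the orifice law integrable for a fully competent valve
  a_eff <- max(effective_area(theta, vp), 1e-6)
  dq <- (dp_valve -
           config$fluid$rho / 2 * q * abs(q) / a_eff^2 / DYN_PER_MMHG) /
    vp$inertance
  dtheta <- valve_rate(theta, dp_valve, vp)
  # hard clip at the theta bounds
  if (theta >= 1 && dtheta > 0) dtheta <- 0
  if (theta <= 0 && dtheta < 0) dtheta <- 0
  stats::setNames(c(d_first, d_p_lv, d_p_sto, dtheta, dq),
                  state_names(config))
}

#' Integrate the circuit to a periodic steady state
#'
#' Integrates the coupled circuit/valve ODE system cycle by cycle (stiff
#' solver, `deSolve` lsoda) until the relative L2 distance between
#' consecutive cycles over all state signals drops below `tol`, then returns
#' the converged cycle sampled on a uniform 1 kHz grid covering one period.
#'
#' @param config A [circuit_config()] object.
#' @param dt Output sampling interval (s); default 1 ms (1 kHz).
#' @param max_cycles Maximum number of cycles to integrate.
#' @param tol Relative L2 cycle-to-cycle convergence tolerance.
#' @param init Optional named initial state (e.g. the `final_state` of a
#'   previous run, for warm restarts).
#' @param hmax Maximum internal step size (s).
#' @param rtol,atol Solver tolerances.
#' @return An object of class `twin_run`: a list with `time` (s, uniform at
#'   `1/dt` Hz over one period), `signals` (data frame with `p_lv_mmHg`,
#'   `p_ao_mmHg`, `q_ao_mL_s`, `theta`, `pdva_cm2`), `period`, `converged`,
#'   `cycles_run`, `tol_achieved`, `final_state` and `config`.
#' @export
run_to_periodic <- function(config, dt = 1e-3, max_cycles = 60, tol = 1e-4,
                            init = NULL, hmax = 1e-3,
                            rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(config, "circuit_config"), dt > 0, tol > 0)
  T <- config$period
  times <- seq(0, T, by = dt)
  if (abs(times[length(times)] - T) > 1e-12) times <- c(times, T)
  rhs <- function(t, y, parms) {
    list(assemble_rhs(config, y, t))
  }
  y <- if (is.null(init)) initial_state(config) else init[state_names(config)]
  prev <- NULL
  converged <- FALSE
  achieved <- Inf
  cycles <- 0L
  sol <- NULL
  for (k in seq_len(max_cycles)) {
    sol <- deSolve::ode(y = y, times = times, func = rhs, parms = NULL,
                        method = "lsoda", hmax = hmax,
                        rtol = rtol, atol = atol)
    cycles <- k
    y <- sol[nrow(sol), -1]
    if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0) {
      stop("ODE integration failed in cycle ", k)
    }
    cur <- sol[, -1, drop = FALSE]
    if (!is.null(prev)) {
      num <- sqrt(sum((cur - prev)^2))
      den <- sqrt(sum(prev^2))
      achieved <- num / den
      if (achieved < tol) {
        converged <- TRUE
        break
      }
    }
    prev <- cur
  }

  # drop the duplicated endpoint: half-open uniform grid [0, T)
  n_keep <- sum(times < T - 1e-12)
  tt <- times[seq_len(n_keep)]
  S <- sol[seq_len(n_keep), , drop = FALSE]
  get <- function(nm) if (nm %in% colnames(S)) S[, nm] else NULL

  p_lv <- get("p_lv")
  p_sto <- get("p_sto")
  if (config$valve$law == "linear") {
    q <- (p_lv - p_sto) / (config$valve$r_linear + config$downstream$r_c)
    theta <- rep(NA_real_, n_keep)
    pdva <- rep(NA_real_, n_keep)
  } else {
    q <- get("q")
    theta <- get("theta")
    pdva <- pdva_proxy(theta, config$valve)
  }
  p_ao <- q * config$downstream$r_c + p_sto

  structure(list(
    time = tt,
    signals = data.frame(
      p_lv_mmHg = p_lv, p_ao_mmHg = p_ao, q_ao_mL_s = q,
      theta = theta, pdva_cm2 = pdva
    ),
    states = S,
    period = T,
    converged = converged,
    cycles_run = cycles,
    tol_achieved = achieved,
    final_state = y,
    config = config
  ), class = "twin_run")
}

#' @export
print.twin_run <- function(x, ...) {
  cat(sprintf("Pulse-duplicator twin run (%s topology)\n",
              x$config$topology))
  cat(sprintf("  period %.4f s, %d samples at %.0f Hz\n", x$period,
              length(x$time), 1 / diff(x$time[1:2])))
  cat(sprintf("  converged: %s after %d cycles (cycle-to-cycle L2 %.2e)\n",
              x$converged, x$cycles_run, x$tol_achieved))
  invisible(x)
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth filter applied forward and backward
#' ([signal::filtfilt()]), so the DC gain is exactly 1 and no phase delay is
#' introduced — the filtering convention of pulse-duplicator data
#' acquisition. Periodic signals are padded by cyclic extension to avoid
#' edge transients.
#'
#' @param x Numeric signal, uniformly sampled.
#' @param fs Sampling rate (Hz).
#' @param fc Cutoff frequency (Hz); must satisfy `fs > 2 * fc`.
#' @param periodic If `TRUE`, treat `x` as one period of a periodic signal
#'   and pad cyclically before filtering.
#' @return Filtered signal of the same length.
#' @export
lowpass_filter <- function(x, fs, fc = 100, periodic = FALSE) {
  if (fs <= 2 * fc) {
    stop(sprintf("sampling rate %g Hz is too coarse for a %g Hz cutoff",
                 fs, fc))
  }
  bf <- signal::butter(4, fc / (fs / 2), type = "low")
  n <- length(x)
  if (periodic) {
    y <- signal::filtfilt(bf, rep(x, 3L))
    return(y[(n + 1):(2 * n)])
  }
  # odd-reflection padding suppresses the zero-initial-state edge transient
  pad <- min(n - 1, ceiling(15 * fs / fc))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filtfilt(bf, xp)
  y[(pad + 1):(pad + n)]
}
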