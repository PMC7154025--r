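#' Uniformly sampled waveform
#'
#' Lightweight container for a single measured or simulated signal: a
#' strictly increasing uniform time grid, values, a unit label, and an
#' optional cycle index.
#'
#' @param time Time grid (s), uniform and strictly increasing.
#' @param value Signal values; finite, same length as `time`.
#' @param unit Unit label (e.g. `"mmHg"`, `"mL/s"`, `"cm^2"`).
#' @param cycle Optional integer cycle marker(s).
#' @return An object of class `waveform`.
#' @export
waveform <- function(time, value, unit = "", cycle = NULL) {
  stopifnot(is.numeric(time), is.numeric(value),
            length(time) == length(value), length(time) >= 2)
  dt <- diff(time)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * mean(dt)) {
    stop("waveform time grid must be uniform and strictly increasing")
  }
  if (any(!is.finite(value))) stop("waveform values must be finite")
  structure(list(time = time, value = value, unit = unit, cycle = cycle),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("waveform: %d samples at %.6g Hz, span %.4g s [%s]\n",
              length(x$time), 1 / diff(x$time[1:2]),
              diff(range(x$time)), x$unit))
  invisible(x)
}

as_waveform <- function(x, time = NULL, unit = "") {
  if (inherits(x, "waveform")) x else waveform(time, x, unit)
}

#' Normalized waveform discrepancy
#'
#' Relative discrepancy between a simulated and a reference (experimental)
#' signal over one period:
#' \deqn{\Delta M_q = \| M^{sim} - M^{exp} \|_{L^q(0,T)} /
#'   \| M^{exp} \|_{L^q(0,T)}, \quad q = 2, \infty.}
#' The L2 norm is computed by trapezoidal quadrature on the reference grid
#' (the simulation is resampled there by linear interpolation); the
#' L-infinity norm is the maximum absolute value.
#'
#' @param m_sim,m_exp [waveform()] objects with overlapping time spans.
#' @param q Norm order: `2` or `Inf`.
#' @return Dimensionless relative discrepancy (multiply by 100 for %).
#' @export
discrepancy <- function(m_sim, m_exp, q = 2) {
  stopifnot(inherits(m_sim, "waveform"), inherits(m_exp, "waveform"))
  if (!q %in% c(2, Inf)) stop("q must be 2 or Inf")
  t_exp <- m_exp$time
  if (min(m_sim$time) > min(t_exp) + 1e-9 ||
      max(m_sim$time) < max(t_exp) - 1e-9) {
    stop("simulation waveform does not cover the reference time span")
  }
  sim <- stats::approx(m_sim$time, m_sim$value, xout = t_exp, rule = 2)$y
  if (q == 2) {
    num <- sqrt(pracma::trapz(t_exp, (sim - m_exp$value)^2))
    den <- sqrt(pracma::trapz(t_exp, m_exp$value^2))
  } else {
    num <- max(abs(sim - m_exp$value))
    den <- max(abs(m_exp$value))
  }
  if (den == 0) stop("reference waveform has zero norm")
  num / den
}

#' Stroke volume of an aortic flow waveform
#'
#' Forward stroke volume: trapezoidal integral of the positive part of the
#' flow over one cycle. The net (signed) volume is available via
#' `type = "net"`; the forward convention is the hydrodynamic-assessment
#' default.
#'
#' @param q_ao A [waveform()] of aortic flow (mL/s) covering one cycle, or a
#'   numeric vector with `time` supplied.
#' @param time Time grid (s) when `q_ao` is a bare numeric vector.
#' @param type `"forward"` (default) or `"net"`.
#' @return Volume (mL).
#' @export
stroke_volume <- function(q_ao, time = NULL, type = c("forward", "net")) {
  type <- match.arg(type)
  wf <- as_waveform(q_ao, time, "mL/s")
  v <- if (type == "forward") pmax(wf$value, 0) else wf$value
  pracma::trapz(wf$time, v)
}

#' Maximum transvalvular pressure difference during forward flow
#'
#' max over \{t : q_ao(t) > 0\} of p_lv(t) - p_ao(t). Diastolic (reverse)
#' pressure differences are excluded by the forward-flow mask.
#'
#' @param p_lv,p_ao,q_ao [waveform()] objects on a common time grid
#'   (ventricular pressure, aortic pressure, aortic flow).
#' @return Pressure difference (mmHg).
#' @export
max_forward_dp <- function(p_lv, p_ao, q_ao) {
  p_lv <- as_waveform(p_lv)
  p_ao <- as_waveform(p_ao)
  q_ao <- as_waveform(q_ao)
  if (max(abs(p_lv$time - p_ao$time)) > 1e-9 ||
      max(abs(p_lv$time - q_ao$time)) > 1e-9) {
    stop("max_forward_dp requires a common time grid")
  }
  fwd <- q_ao$value > 0
  if (!any(fwd)) stop("no forward-flow samples in the cycle")
  max(p_lv$value[fwd] - p_ao$value[fwd])
}

#' Peak Reynolds number of the test section
#'
#' Re_peak = rho Q_peak D / (mu A) with A = pi D^2 / 4 the cross-sectional
#' area of the aortic test section; viscosity is converted from cP to poise.
#'
#' @param q_peak Peak flow rate (mL/s).
#' @param d Test-section diameter (cm).
#' @param fluid A [fluid_properties()] object.
#' @return Dimensionless peak Reynolds number.
#' @export
re_peak <- function(q_peak, d, fluid = fluid_properties()) {
  stopifnot(q_peak >= 0, d > 0)
  a <- pi * d^2 / 4
  fluid$rho * q_peak * d / (fluid$mu * POISE_PER_CP * a)
}

#' Pointwise ensemble statistics of phase-aligned cycles
#'
#' Mean waveform and central 95% band (2.5/97.5 percentiles) across a set of
#' cycles sampled on a common phase-aligned grid — the summary drawn as the
#' shaded band around average experimental waveforms.
#'
#' @param cycles List of [waveform()] objects on a common grid, or a numeric
#'   matrix with one column per cycle.
#' @param time Time grid when `cycles` is a matrix.
#' @param level Band coverage (default 0.95).
#' @return List with `time`, `mean`, `lower`, `upper` and `n`.
#' @export
ensemble_stats <- function(cycles, time = NULL, level = 0.95) {
  if (is.list(cycles) && !is.matrix(cycles)) {
    stopifnot(length(cycles) >= 2)
    time <- cycles[[1]]$time
    for (w in cycles) {
      if (max(abs(w$time - time)) > 1e-9) {
        stop("all cycles must share a common phase-aligned grid")
      }
    }
    M <- vapply(cycles, function(w) w$value, numeric(length(time)))
  } else {
    M <- as.matrix(cycles)
    stopifnot(ncol(M) >= 2, !is.null(time), nrow(M) == length(time))
  }
  alpha <- (1 - level) / 2
  list(time = time,
       mean = rowMeans(M),
       lower = apply(M, 1, stats::quantile, probs = alpha, names = FALSE),
       upper = apply(M, 1, stats::quantile, probs = 1 - alpha,
                     names = FALSE),
       n = ncol(M))
}
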