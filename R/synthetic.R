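# Synthetic-experiment generator: drives the 0D twin to the preset operating
# point, then emulates a multi-cycle pulse-duplicator recording with
# cycle-to-cycle variability, sensor noise, platform filtering and PDVA
# flutter.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  force(code)
}

run_scalars <- function(run) {
  s <- run$signals
  wq <- waveform(run$time, s$q_ao_mL_s, "mL/s")
  list(
    sv = stroke_volume(wq),
    q_peak = max(s$q_ao_mL_s),
    dp_max = max_forward_dp(
      waveform(run$time, s$p_lv_mmHg, "mmHg"),
      waveform(run$time, s$p_ao_mmHg, "mmHg"), wq)
  )
}

# Rescale a valve surrogate's orifice areas by a common factor.
scale_valve_area <- function(valve, factor) {
  valve$a_max <- valve$a_max * factor
  valve$a_leak <- valve$a_leak * factor
  valve$a_proj_max <- valve$a_proj_max * factor
  valve
}

#' Calibrate the pump driver (and optionally the orifice area) of the twin
#'
#' Fixed-point calibration of the driver amplitude and systolic width so
#' that the converged periodic cycle of the coupled circuit/valve model
#' attains the target forward stroke volume and peak aortic flow; when a
#' target peak forward pressure difference is supplied, the effective
#' orifice area is co-calibrated through the Bernoulli law. Runs are warm
#' restarted from the previous converged state, so each iteration costs only
#' a few cycles.
#'
#' @param config A [circuit_config()] object (its `driver` supplies the
#'   starting point).
#' @param targets List with `sv` (mL), `q_peak` (mL/s) and optionally
#'   `dp_max` (mmHg).
#' @param tol Relative tolerance on each target.
#' @param max_iter Maximum number of calibration iterations.
#' @param run_tol Cycle-convergence tolerance used during the iterations;
#'   the final run uses `final_tol`.
#' @param final_tol Cycle-convergence tolerance of the returned run.
#' @param quiet Suppress per-iteration messages.
#' @return List of class `twin_calibration`: `config` (calibrated), `run`
#'   (final converged [run_to_periodic()] output), `achieved` (named
#'   scalars), `targets`, `iterations`, `converged`.
#' @export
calibrate_driver <- function(config, targets, tol = 8e-4, max_iter = 20,
                             run_tol = 3e-4, final_tol = 1e-4,
                             quiet = TRUE) {
  stopifnot(inherits(config, "circuit_config"),
            is.numeric(targets$sv), is.numeric(targets$q_peak))
  if (targets$q_peak <= targets$sv * config$hr_bpm / 60) {
    stop("infeasible targets: peak flow must exceed the cycle-mean flow")
  }
  warm <- NULL
  converged <- FALSE
  it <- 0L
  run <- NULL
  for (it in seq_len(max_iter)) {
    run <- run_to_periodic(config, tol = run_tol, init = warm)
    warm <- run$final_state
    got <- run_scalars(run)
    r_q <- targets$q_peak / got$q_peak
    r_sv <- targets$sv / got$sv
    errs <- c(abs(r_q - 1), abs(r_sv - 1))
    r_dp <- 1
    if (!is.null(targets$dp_max)) {
      r_dp <- got$dp_max / targets$dp_max
      errs <- c(errs, abs(r_dp - 1))
    }
    if (!quiet) {
      message(sprintf(
        "  calib %2d: SV %.2f, Qpk %.1f, dPmax %.2f (errs %s)",
        it, got$sv, got$q_peak, got$dp_max,
        paste(signif(errs, 2), collapse = " ")))
    }
    if (all(errs < tol)) {
      converged <- TRUE
      break
    }
    config$driver$amp <- config$driver$amp * r_q
    # the ejected volume per unit peak flow scales with the pulse width and
    # its flatness; widen first, flatten once the width cap binds
    shape <- if (is.null(config$driver$shape)) 1 else config$driver$shape
    width <- config$driver$width * r_sv / r_q
    cap <- 0.45 * config$period
    if (width > cap) {
      shape <- shape * (width / cap)^(-2.5)
    } else if (width < 0.08) {
      shape <- shape * (width / 0.08)^(-2.5)
    }
    config$driver$width <- min(max(width, 0.08), cap)
    config$driver$shape <- min(max(shape, 0.25), 4)
    if (!is.null(targets$dp_max)) {
      config$valve <- scale_valve_area(config$valve, sqrt(r_dp))
    }
  }
  run <- run_to_periodic(config, tol = final_tol, init = warm,
                         max_cycles = 80)
  structure(list(
    config = config, run = run, achieved = run_scalars(run),
    targets = targets, iterations = it, converged = converged
  ), class = "twin_calibration")
}

#' Generate a calibrated pump driver for an experiment preset
#'
#' Builds the circuit for the preset's platform, sets the valve effective
#' orifice area from the preset peak flow and peak pressure-difference
#' targets, and calibrates the pump source so the coupled model reproduces
#' the preset forward stroke volume and peak flow. The porcine platform uses
#' a pressure-source driver; the pericardial platform uses a zero-net-volume
#' piston flow source plus a constant atrial pressure feeding the mitral
#' diode.
#'
#' @param preset An [experiment_preset()] object.
#' @param ... Passed to [calibrate_driver()].
#' @return A `twin_calibration` object (see [calibrate_driver()]); its
#'   `config$driver` is the calibrated driver.
#' @export
gen_pump_driver <- function(preset, ...) {
  stopifnot(inherits(preset, "experiment_preset"))
  cfgfile <- preset$config
  valve <- valve_preset(preset$valve, cfgfile, dp_peak = preset$dp_mean)
  circ <- circuit_preset(preset$valve, cfgfile, valve = valve)
  calibrate_driver(circ,
                   targets = list(sv = preset$sv_mean,
                                  q_peak = preset$q_peak,
                                  dp_max = preset$dp_mean), ...)
}

#' Generate a synthetic pulse-duplicator experiment
#'
#' Runs the calibrated twin and emulates `n_cycles` consecutive measured
#' cycles: a single multiplicative amplitude factor per cycle (independently
#' for flow and for pressures, with coefficients of variation taken from the
#' preset SD/mean ratios), additive white sensor noise, zero-phase 100 Hz
#' Butterworth filtering of the channels the platform filters, and a damped
#' systolic flutter oscillation added to the (never filtered) PDVA signal.
#' All randomness flows through the single `seed`.
#'
#' @param preset An [experiment_preset()] object.
#' @param n_cycles Number of cycles to generate (default from the preset).
#' @param seed Integer seed; recorded in the dataset metadata.
#' @param noise If `FALSE`, all stochastic components are disabled and every
#'   cycle equals the twin's converged cycle.
#' @param calibration Optionally a precomputed [gen_pump_driver()] result,
#'   to avoid re-calibrating.
#' @return An object of class `synthetic_dataset`: `time` (one-cycle grid,
#'   1 kHz), `cycles` (long data frame with `cycle_index` and the waveform
#'   CSV columns), `mean` (noise-free base cycle), `preset`, `seed`,
#'   `calibration`, `version`.
#' @export
gen_experiment <- function(preset, n_cycles = NULL, seed = 1L,
                           noise = TRUE, calibration = NULL) {
  stopifnot(inherits(preset, "experiment_preset"))
  if (is.null(n_cycles)) n_cycles <- preset$n_cycles
  stopifnot(n_cycles >= 1)
  if (is.null(calibration)) calibration <- gen_pump_driver(preset)
  run <- calibration$run
  tt <- run$time
  n <- length(tt)
  fs <- 1 / (tt[2] - tt[1])
  base <- run$signals

  cv_q <- preset$sv_sd / preset$sv_mean
  cv_p <- preset$dp_sd / preset$dp_mean
  sn <- preset$sensor_noise
  fl <- preset$flutter

  sim <- with_local_seed(seed, {
    f_q <- if (noise) stats::rnorm(n_cycles, 1, cv_q) else rep(1, n_cycles)
    f_p <- if (noise) stats::rnorm(n_cycles, 1, cv_p) else rep(1, n_cycles)
    phase <- if (noise) stats::runif(n_cycles, 0, 2 * pi) else rep(0, n_cycles)
    eps <- function(sd) {
      if (noise) stats::rnorm(n * n_cycles, 0, sd) else numeric(n * n_cycles)
    }
    q_long <- rep(base$q_ao_mL_s, n_cycles) *
      rep(f_q, each = n) + eps(sn$flow_ml_s)
    plv_long <- rep(base$p_lv_mmHg, n_cycles) *
      rep(f_p, each = n) + eps(sn$pressure_mmhg)
    pao_long <- rep(base$p_ao_mmHg, n_cycles) *
      rep(f_p, each = n) + eps(sn$pressure_mmhg)

    # PDVA flutter: damped oscillation launched at valve opening, gated by
    # the opening fraction so it lives on the systolic plateau
    onset <- which(base$theta > 0.5)[1]
    t_loc <- pmax(tt - tt[max(onset, 1)], 0)
    envel <- exp(-t_loc / fl$decay_s) * (base$theta > 0.5)
    pdva_long <- rep(base$pdva_cm2, n_cycles)
    if (noise) {
      flut <- as.vector(vapply(seq_len(n_cycles), function(i) {
        fl$amp_frac * run$config$valve$a_proj_max * envel *
          sin(2 * pi * fl$freq_hz * t_loc + phase[i]) * base$theta
      }, numeric(n)))
      pdva_long <- pdva_long + flut + eps(sn$pdva_cm2)
    }
    list(q = q_long, plv = plv_long, pao = pao_long, pdva = pdva_long)
  })

  # noise = FALSE disables the whole measurement-emulation chain (jitter,
  # sensor noise, flutter and filtering), leaving the bare twin cycles
  filt <- function(x, apply_it) {
    if (!apply_it || !noise) return(x)
    lowpass_filter(x, fs = fs, fc = preset$filter_cutoff, periodic = TRUE)
  }
  sim$q <- filt(sim$q, preset$filter_flow)
  sim$plv <- filt(sim$plv, preset$filter_pressure)
  sim$pao <- filt(sim$pao, preset$filter_pressure)

  cycles <- data.frame(
    time_s = rep(tt, n_cycles),
    p_lv_mmHg = sim$plv,
    p_ao_mmHg = sim$pao,
    q_ao_mL_s = sim$q,
    pdva_cm2 = sim$pdva,
    cycle_index = rep(seq_len(n_cycles), each = n)
  )
  structure(list(
    time = tt,
    cycles = cycles,
    mean = base,
    preset = preset,
    seed = as.integer(seed),
    calibration = calibration,
    version = as.character(utils::packageVersion("valvetwin"))
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  n_cyc <- length(unique(x$cycles$cycle_index))
  cat(sprintf(
    "Synthetic pulse-duplicator dataset: %s valve, %d cycles, seed %d\n",
    x$preset$valve, n_cyc, x$seed))
  cat(sprintf("  %d samples per cycle at %.0f Hz\n", length(x$time),
              1 / diff(x$time[1:2])))
  invisible(x)
}

#' Per-cycle waveforms of one signal
#'
#' @param dataset A `synthetic_dataset`.
#' @param signal One of `"p_lv_mmHg"`, `"p_ao_mmHg"`, `"q_ao_mL_s"`,
#'   `"pdva_cm2"`.
#' @return List of [waveform()] objects, one per cycle.
#' @export
dataset_cycles <- function(dataset, signal = "q_ao_mL_s") {
  stopifnot(inherits(dataset, "synthetic_dataset"),
            signal %in% c("p_lv_mmHg", "p_ao_mmHg", "q_ao_mL_s",
                          "pdva_cm2"))
  unit <- c(p_lv_mmHg = "mmHg", p_ao_mmHg = "mmHg",
            q_ao_mL_s = "mL/s", pdva_cm2 = "cm^2")[[signal]]
  lapply(split(dataset$cycles[[signal]], dataset$cycles$cycle_index),
         function(v) waveform(dataset$time, v, unit))
}

#' Ensemble-mean waveform of one signal
#'
#' @inheritParams dataset_cycles
#' @return A [waveform()] holding the pointwise cycle-ensemble mean.
#' @export
dataset_mean_waveform <- function(dataset, signal = "q_ao_mL_s") {
  cyc <- dataset_cycles(dataset, signal)
  if (length(cyc) == 1) return(cyc[[1]])
  st <- ensemble_stats(cyc)
  waveform(st$time, st$mean, cyc[[1]]$unit)
}

#' Generate a synthetic biaxial tensile-test dataset
#'
#' Evaluates the incompressible plane-stress biaxial response of a material
#' on a set of loading protocols and adds multiplicative measurement noise.
#' The default protocols — equibiaxial stretching plus two constrained
#' strip-biaxial paths — make the dispersion and fiber-exponent parameters
#' identifiable.
#'
#' @param material A [material_params()] object.
#' @param protocols Named list of protocols, each a list with `lam1` and
#'   `lam2` vectors of equal length.
#' @param noise_cv Coefficient of variation of multiplicative noise.
#' @param seed Integer seed.
#' @param fiber_angle In-plane fiber angle (radians).
#' @return Data frame with columns `protocol_id`, `lam1`, `lam2`,
#'   `sigma11_kPa`, `sigma22_kPa`.
#' @export
gen_biaxial_dataset <- function(material,
                                protocols = default_biaxial_protocols(),
                                noise_cv = 0, seed = 1L, fiber_angle = 0) {
  stopifnot(inherits(material, "material_params"), noise_cv >= 0)
  rows <- lapply(names(protocols), function(id) {
    pr <- protocols[[id]]
    stopifnot(length(pr$lam1) == length(pr$lam2))
    sig <- t(mapply(function(l1, l2) {
      plane_stress_biaxial(material, l1, l2, fiber_angle)[1:2]
    }, pr$lam1, pr$lam2))
    data.frame(protocol_id = id, lam1 = pr$lam1, lam2 = pr$lam2,
               sigma11_kPa = sig[, 1], sigma22_kPa = sig[, 2])
  })
  out <- do.call(rbind, rows)
  if (noise_cv > 0) {
    out <- with_local_seed(seed, {
      m <- length(out$sigma11_kPa)
      out$sigma11_kPa <- out$sigma11_kPa * stats::rnorm(m, 1, noise_cv)
      out$sigma22_kPa <- out$sigma22_kPa * stats::rnorm(m, 1, noise_cv)
      out
    })
  }
  rownames(out) <- NULL
  out
}

#' @rdname gen_biaxial_dataset
#' @param lam_max Largest stretch of the protocols.
#' @param n_points Points per protocol.
#' @export
default_biaxial_protocols <- function(lam_max = 1.15, n_points = 30) {
  lam <- seq(1, lam_max, length.out = n_points)
  list(
    equibiaxial = list(lam1 = lam, lam2 = lam),
    strip_1 = list(lam1 = lam, lam2 = rep(1, n_points)),
    strip_2 = list(lam1 = rep(1, n_points), lam2 = lam)
  )
}
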