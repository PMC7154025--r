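# High-level pipeline entry points: simulate the calibrated twin, generate a
# synthetic experiment, compare runs to datasets, fit materials from files.

#' Simulate the calibrated 0D twin for a valve preset
#'
#' Builds the platform circuit for the preset, sets the valve effective
#' orifice area from the preset peak flow and peak simulated pressure
#' difference ([calibrate_eoa()]), calibrates the pump driver against the
#' target forward stroke volume and peak flow, and returns the converged
#' periodic cycle with its scalar summary (stroke volume, maximum
#' forward-flow pressure difference, peak flow, peak Reynolds number).
#'
#' @param preset `"porcine"` or `"pericardial"`.
#' @param config A [load_config()] configuration.
#' @param targets Optional list with `sv` (mL) and `q_peak` (mL/s) to
#'   calibrate the driver against — e.g. values measured from a synthetic
#'   experimental mean flow waveform. Defaults to the preset's experimental
#'   targets.
#' @param fluid Test fluid (default saline).
#' @param ... Passed to [calibrate_driver()].
#' @return List of class `twin_simulation`: `run`, `summary`, `calibration`.
#' @export
simulate_twin <- function(preset = c("porcine", "pericardial"),
                          config = load_config(), targets = NULL,
                          fluid = fluid_preset("saline", config), ...) {
  preset <- check_preset_name(match.arg(preset))
  circ <- circuit_preset(preset, config, fluid = fluid)
  if (is.null(targets)) {
    ep <- experiment_preset(preset, config)
    targets <- list(sv = ep$sv_mean, q_peak = ep$q_peak)
  }
  targets$dp_max <- NULL  # EOA stays at its Bernoulli calibration
  cal <- calibrate_driver(circ, targets, ...)
  got <- cal$achieved
  d <- config$test_section$diameter_cm
  structure(list(
    run = cal$run,
    summary = list(
      stroke_volume_ml = got$sv,
      dp_max_mmhg = got$dp_max,
      q_peak_ml_s = got$q_peak,
      re_peak = re_peak(got$q_peak, d, fluid),
      converged = cal$run$converged,
      calibration_converged = cal$converged
    ),
    calibration = cal
  ), class = "twin_simulation")
}

#' @export
print.twin_simulation <- function(x, ...) {
  s <- x$summary
  cat("Calibrated 0D pulse-duplicator twin\n")
  cat(sprintf("  forward stroke volume: %.2f mL\n", s$stroke_volume_ml))
  cat(sprintf("  max forward dP:        %.2f mmHg\n", s$dp_max_mmhg))
  cat(sprintf("  peak flow:             %.1f mL/s\n", s$q_peak_ml_s))
  cat(sprintf("  Re_peak:               %.0f\n", s$re_peak))
  invisible(x)
}

#' Generate and optionally persist a synthetic experiment
#'
#' Convenience wrapper over [experiment_preset()], [gen_experiment()] and
#' [write_waveforms()].
#'
#' @param preset `"porcine"` or `"pericardial"`, or an
#'   [experiment_preset()] object.
#' @param n_cycles Number of cycles.
#' @param seed Integer seed.
#' @param out_csv Optional path; when given, the dataset and its JSON
#'   metadata sidecar are written there.
#' @param config A [load_config()] configuration.
#' @param ... Passed to [gen_experiment()].
#' @return The `synthetic_dataset`, invisibly when written to disk.
#' @export
generate_experiment <- function(preset = "porcine", n_cycles = NULL,
                                seed = 1L, out_csv = NULL,
                                config = load_config(), ...) {
  if (!inherits(preset, "experiment_preset")) {
    preset <- experiment_preset(preset, config)
  }
  ds <- gen_experiment(preset, n_cycles = n_cycles, seed = seed, ...)
  if (!is.null(out_csv)) {
    write_waveforms(ds, out_csv)
    return(invisible(ds))
  }
  ds
}

# Index of valve-opening onset on a periodic flow cycle: first upcrossing of
# 5% of the peak forward flow.
opening_onset_index <- function(q) {
  thr <- 0.05 * max(q)
  above <- q > thr
  up <- which(above & !c(above[length(above)], above[-length(above)]))
  if (!length(up)) 1L else up[1]
}

circular_shift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) x else c(x[(n - k + 1):n], x[1:(n - k)])
}

#' Compare a twin simulation with an experimental dataset
#'
#' Phase-aligns the simulated cycle to the experimental ensemble mean at the
#' beginning of valve opening (circular shift of the periodic cycle), then
#' computes the normalized L2 and L-infinity discrepancies of P_LV, P_Ao and
#' Q_Ao plus the scalar summaries: forward stroke volumes, maximum
#' forward-flow pressure differences, and peak Reynolds numbers.
#'
#' @param sim A `twin_simulation` (or a bare `twin_run`).
#' @param dataset A `synthetic_dataset` (generated or read from CSV).
#' @param align Align on valve-opening onset before computing norms.
#' @param d Test-section diameter (cm) for the Reynolds numbers.
#' @param fluid Test fluid.
#' @return List of class `comparison_report`: `norms` (data frame, percent),
#'   `scalars`, `alignment_shift_s`.
#' @export
compare_waveforms <- function(sim, dataset, align = TRUE, d = 2.8,
                              fluid = fluid_properties()) {
  run <- if (inherits(sim, "twin_simulation")) sim$run else sim
  stopifnot(inherits(run, "twin_run"),
            inherits(dataset, "synthetic_dataset"))
  exp_mean <- lapply(
    c(p_lv_mmHg = "p_lv_mmHg", p_ao_mmHg = "p_ao_mmHg",
      q_ao_mL_s = "q_ao_mL_s"),
    function(s) dataset_mean_waveform(dataset, s))
  tt <- dataset$time
  if (length(tt) != length(run$time) || max(abs(tt - run$time)) > 1e-9) {
    stop("simulation and experiment grids differ beyond tolerance; ",
         "resample one of them first")
  }
  shift <- 0L
  if (align) {
    shift <- opening_onset_index(exp_mean$q_ao_mL_s$value) -
      opening_onset_index(run$signals$q_ao_mL_s)
  }
  sim_sig <- lapply(run$signals[c("p_lv_mmHg", "p_ao_mmHg", "q_ao_mL_s")],
                    circular_shift, k = shift)

  norms <- do.call(rbind, lapply(
    c("p_lv_mmHg", "p_ao_mmHg", "q_ao_mL_s"), function(s) {
      ws <- waveform(tt, sim_sig[[s]])
      we <- exp_mean[[s]]
      data.frame(signal = sub("_mmHg|_mL_s", "", s),
                 l2_pct = 100 * discrepancy(ws, we, 2),
                 linf_pct = 100 * discrepancy(ws, we, Inf))
    }))

  wq_exp <- exp_mean$q_ao_mL_s
  sv_exp_cycles <- vapply(dataset_cycles(dataset, "q_ao_mL_s"),
                          stroke_volume, numeric(1))
  scal <- list(
    sv_sim_ml = stroke_volume(waveform(tt, sim_sig$q_ao_mL_s)),
    sv_exp_ml = mean(sv_exp_cycles),
    sv_exp_sd_ml = stats::sd(sv_exp_cycles),
    dp_max_sim_mmhg = max_forward_dp(
      waveform(tt, sim_sig$p_lv_mmHg), waveform(tt, sim_sig$p_ao_mmHg),
      waveform(tt, sim_sig$q_ao_mL_s)),
    dp_max_exp_mmhg = max_forward_dp(
      exp_mean$p_lv_mmHg, exp_mean$p_ao_mmHg, wq_exp),
    re_peak_sim = re_peak(max(sim_sig$q_ao_mL_s), d, fluid),
    re_peak_exp = re_peak(max(wq_exp$value), d, fluid)
  )
  structure(list(norms = norms, scalars = scal,
                 alignment_shift_s = shift * (tt[2] - tt[1])),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Simulation vs experiment discrepancy report\n")
  cat(sprintf("  alignment shift: %+.3f s (valve-opening onset)\n",
              x$alignment_shift_s))
  df <- x$norms
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-5s  L2 %5.1f %%   Linf %5.1f %%\n",
                df$signal[i], df$l2_pct[i], df$linf_pct[i]))
  }
  s <- x$scalars
  cat(sprintf("  stroke volume: sim %.1f mL, exp %.1f +/- %.1f mL\n",
              s$sv_sim_ml, s$sv_exp_ml, s$sv_exp_sd_ml))
  cat(sprintf("  max forward dP: sim %.1f, exp %.1f mmHg\n",
              s$dp_max_sim_mmhg, s$dp_max_exp_mmhg))
  cat(sprintf("  Re_peak: sim %.0f, exp %.0f\n",
              s$re_peak_sim, s$re_peak_exp))
  invisible(x)
}

#' Serialize a comparison report
#'
#' @param report A `comparison_report`.
#' @param path Output path; `.json` or `.csv` (norm table only) by
#'   extension.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(norms = report$norms, scalars = report$scalars,
           alignment_shift_s = report$alignment_shift_s),
      path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    utils::write.csv(report$norms, path, row.names = FALSE)
  }
  invisible(path)
}

#' Fit leaflet material parameters from a biaxial CSV file
#'
#' @param path CSV with the biaxial schema (`protocol_id`, `lam1`, `lam2`,
#'   `sigma11_kPa`, `sigma22_kPa`).
#' @param init Starting [material_params()].
#' @param ... Passed to [fit_material_params()].
#' @return A `material_fit` object.
#' @export
fit_material_file <- function(path, init, ...) {
  df <- utils::read.csv(path)
  fit_material_params(df, init, ...)
}
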