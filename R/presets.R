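#' Load the twin configuration
#'
#' Reads the structured YAML configuration holding all circuit, material,
#' valve, fluid and experiment parameters. With no argument the packaged
#' default configuration is returned; a user file is validated against the
#' expected top-level blocks.
#'
#' @param path Path to a YAML configuration, or `NULL` for the packaged
#'   default.
#' @return Nested named list of class `twin_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_config.yaml",
                        package = "valvetwin")
  }
  cfg <- yaml::read_yaml(path)
  need <- c("hr_bpm", "test_section", "fluid", "material", "circuit",
            "valve", "experiment", "driver_init", "integration")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    stop("configuration is missing block(s): ", paste(miss, collapse = ", "))
  }
  structure(cfg, class = c("twin_config", "list"))
}

check_preset_name <- function(name) {
  if (!name %in% c("porcine", "pericardial")) {
    stop("unknown valve preset '", name,
         "'; use \"porcine\" or \"pericardial\"")
  }
  name
}

#' Material, circuit, valve, fluid and experiment presets
#'
#' Accessors constructing ready-to-use parameter objects from a
#' configuration. `material_preset` returns the fitted constitutive
#' constants for the glutaraldehyde-fixed porcine aortic or bovine
#' pericardial leaflets; `circuit_preset` builds the full
#' [circuit_config()] for the corresponding experimental platform with the
#' valve surrogate attached; `valve_preset` builds the [valve_params()]
#' with the effective orifice area calibrated from the preset peak flow and
#' peak simulated gradient via [calibrate_eoa()]; `fluid_preset` returns
#' saline or the Newtonian blood analogue.
#'
#' @param name `"porcine"` or `"pericardial"` (fluid: `"saline"` or
#'   `"blood_analogue"`).
#' @param config A configuration from [load_config()] (default packaged
#'   values).
#' @param dp_peak Peak forward gradient (mmHg) used for the EOA calibration;
#'   defaults to the preset's simulated value.
#' @return See Details.
#' @name presets
NULL

#' @rdname presets
#' @export
material_preset <- function(name = c("porcine", "pericardial"),
                            config = load_config()) {
  name <- check_preset_name(match.arg(name))
  m <- config$material[[name]]
  ang <- m$fiber_angle_deg * pi / 180
  mp <- material_params(c10 = m$c10_kpa, c01 = m$c01, k1 = m$k1_mpa,
                        k2 = m$k2, kappa = m$kappa,
                        e0 = c(cos(ang), sin(ang), 0),
                        beta_vol = config$material$beta_mpa)
  mp$fiber_angle <- ang
  mp
}

#' @rdname presets
#' @export
fluid_preset <- function(name = c("saline", "blood_analogue"),
                         config = load_config()) {
  name <- match.arg(name)
  f <- config$fluid[[name]]
  fluid_properties(rho = f$rho, mu = f$mu)
}

#' @rdname presets
#' @export
valve_preset <- function(name = c("porcine", "pericardial"),
                         config = load_config(), dp_peak = NULL,
                         fluid = fluid_preset("saline", config)) {
  name <- check_preset_name(match.arg(name))
  v <- config$valve[[name]]
  g <- config$valve
  if (is.null(dp_peak)) dp_peak <- v$dp_sim_mmhg
  a_max <- calibrate_eoa(v$q_peak_ml_s, dp_peak, fluid)
  valve_params(
    a_max = a_max, a_leak = g$leak_frac * a_max,
    k_open = g$k_open, k_close = g$k_close, inertance = g$inertance,
    cap_radius = v$cap_radius_cm, thickness = v$thickness_cm,
    material = material_preset(v$material, config),
    a_proj_max = a_max / g$discharge_coeff
  )
}

#' @rdname presets
#' @param valve Optional [valve_params()] overriding the preset valve.
#' @export
circuit_preset <- function(name = c("porcine", "pericardial"),
                           config = load_config(), valve = NULL,
                           fluid = fluid_preset("saline", config)) {
  name <- check_preset_name(match.arg(name))
  cc <- config$circuit[[name]]
  if (is.null(valve)) valve <- valve_preset(name, config, fluid = fluid)
  ds <- rcr_windkessel(cc$downstream$r_c, cc$downstream$r_p,
                       cc$downstream$c)
  driver <- config$driver_init[[name]]
  circuit_config(
    topology = name, upstream = cc$upstream, downstream = ds,
    valve = valve, fluid = fluid, driver = driver,
    hr_bpm = config$hr_bpm,
    c_lv = if (!is.null(cc$c_lv)) cc$c_lv else 0.02
  )
}

#' Synthetic-experiment preset
#'
#' Study conditions for generating a synthetic pulse-duplicator dataset: the
#' pulse rate, the target per-cycle forward stroke volume (mean and SD), the
#' target maximum forward-flow pressure difference (mean and SD), the target
#' peak flow, and the platform-specific filtering flags. The porcine
#' platform filters pressure and flow at 100 Hz; the pericardial (FDA)
#' platform filters flow only. PDVA is never filtered.
#'
#' @param name `"porcine"` or `"pericardial"`.
#' @param config A configuration from [load_config()].
#' @param n_cycles Default number of consecutive cycles.
#' @return An object of class `experiment_preset`.
#' @export
experiment_preset <- function(name = c("porcine", "pericardial"),
                              config = load_config(), n_cycles = NULL) {
  name <- check_preset_name(match.arg(name))
  e <- config$experiment[[name]]
  g <- config$experiment
  stopifnot(e$sv_mean_ml > 0, e$sv_sd_ml >= 0,
            e$dp_mean_mmhg > 0, e$dp_sd_mmhg >= 0, e$q_peak_ml_s > 0)
  structure(list(
    valve = name,
    hr_bpm = config$hr_bpm,
    sv_mean = e$sv_mean_ml, sv_sd = e$sv_sd_ml,
    dp_mean = e$dp_mean_mmhg, dp_sd = e$dp_sd_mmhg,
    q_peak = e$q_peak_ml_s,
    filter_cutoff = g$filter_cutoff_hz,
    filter_pressure = isTRUE(e$filter_pressure),
    filter_flow = isTRUE(e$filter_flow),
    flutter = g$pdva_flutter,
    sensor_noise = g$sensor_noise,
    n_cycles = if (is.null(n_cycles)) g$n_cycles else n_cycles,
    config = config
  ), class = "experiment_preset")
}

#' @export
print.experiment_preset <- function(x, ...) {
  cat(sprintf("Synthetic pulse-duplicator experiment preset: %s valve\n",
              x$valve))
  cat(sprintf("  %d bpm, SV %.1f +/- %.1f mL, dP_max %.1f +/- %.1f mmHg,",
              x$hr_bpm, x$sv_mean, x$sv_sd, x$dp_mean, x$dp_sd))
  cat(sprintf(" Q_peak %.1f mL/s\n", x$q_peak))
  cat(sprintf("  filtering at %g Hz: pressure %s, flow %s, PDVA never\n",
              x$filter_cutoff, x$filter_pressure, x$filter_flow))
  invisible(x)
}
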