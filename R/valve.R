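#' Zero-dimensional valve surrogate parameters
#'
#' The 3D fluid--structure-interaction valve is replaced by a lumped
#' surrogate: an opening fraction `theta` in [0, 1] driven by the
#' transvalvular pressure difference (a Mynard-type rate law), a linear
#' effective-orifice area in `theta`, and a Bernoulli orifice pressure--flow
#' law with a small inertance. A quasi-static spherical-cap membrane model
#' exercises the leaflet constitutive law under diastolic load.
#'
#' @param a_max Maximal effective orifice area (cm^2), > `a_leak`.
#' @param a_leak Closed-valve leak area (cm^2), >= 0. Default keeps the valve
#'   nearly competent (0.1% of `a_max`).
#' @param k_open,k_close Opening/closing rate coefficients (1/(mmHg s)). The
#'   defaults give opening/closing time constants of roughly 10--20 ms at
#'   typical transvalvular pressures.
#' @param inertance Blood-column inertance (mmHg s^2/mL).
#' @param cap_radius Radius of the loaded leaflet cap (cm).
#' @param thickness Leaflet thickness (cm).
#' @param material A [material_params()] object for the membrane model, or
#'   `NULL` if only the hydraulic surrogate is used.
#' @param law `"bernoulli"` for the orifice law, `"linear"` for a fixed
#'   linear resistance (used for circuit verification against closed-form
#'   linear solutions).
#' @param r_linear Resistance (mmHg s/mL) when `law = "linear"`.
#' @param a_proj_max Projected-area scale for the PDVA proxy (cm^2); defaults
#'   to `a_max / 0.7` (discharge-coefficient convention, documented as a
#'   surrogate choice).
#' @return An object of class `valve_params`.
#' @export
valve_params <- function(a_max, a_leak = 0.001 * a_max,
                         k_open = 5, k_close = 5,
                         inertance = 5e-4,
                         cap_radius = 1.25, thickness = 0.04,
                         material = NULL,
                         law = c("bernoulli", "linear"),
                         r_linear = NULL,
                         a_proj_max = a_max / 0.7) {
  law <- match.arg(law)
  stopifnot(a_max > a_leak, a_leak >= 0, k_open > 0, k_close > 0,
            inertance >= 0, cap_radius > 0, thickness > 0)
  if (law == "linear") stopifnot(is.numeric(r_linear), r_linear > 0)
  structure(list(
    a_max = a_max, a_leak = a_leak,
    k_open = k_open, k_close = k_close,
    inertance = inertance,
    cap_radius = cap_radius, thickness = thickness,
    material = material, law = law, r_linear = r_linear,
    a_proj_max = a_proj_max
  ), class = "valve_params")
}

#' Opening-fraction rate law
#'
#' d(theta)/dt = k_open (1 - theta) dp for dp >= 0 and
#' k_close theta dp for dp < 0, clipped so that theta cannot leave [0, 1].
#'
#' @param theta Opening fraction in [0, 1].
#' @param dp Transvalvular pressure difference p_up - p_down (mmHg).
#' @param params A [valve_params()] object.
#' @return Rate d(theta)/dt (1/s); vectorized over `theta` and `dp`.
#' @export
valve_rate <- function(theta, dp, params) {
  theta <- pmin(pmax(theta, 0), 1)
  ifelse(dp >= 0,
         params$k_open * (1 - theta) * dp,
         params$k_close * theta * dp)
}

#' Effective orifice area at a given opening fraction
#'
#' Linear interpolation between the leak area (closed) and the maximal
#' effective orifice area (fully open).
#'
#' @inheritParams valve_rate
#' @return Area (cm^2); vectorized over `theta`.
#' @export
effective_area <- function(theta, params) {
  params$a_leak + (params$a_max - params$a_leak) * pmin(pmax(theta, 0), 1)
}

#' Transvalvular pressure difference of the orifice law
#'
#' Bernoulli orifice drop plus inertial term:
#' dp = (rho/2) q |q| / A_eff^2 (converted dyn/cm^2 -> mmHg)
#' + inertance dq/dt.
#'
#' @param q Valve flow (mL/s).
#' @param dqdt Flow time derivative (mL/s^2).
#' @inheritParams valve_rate
#' @param fluid A [fluid_properties()] object.
#' @return Pressure difference (mmHg); vectorized.
#' @export
valve_pressure_flow <- function(q, dqdt, theta, fluid, params) {
  a <- effective_area(theta, params)
  fluid$rho / 2 * q * abs(q) / a^2 / DYN_PER_MMHG + params$inertance * dqdt
}

#' Calibrate the effective orifice area from peak flow and peak gradient
#'
#' Inverts the Bernoulli orifice law at peak flow (where the inertial term
#' vanishes): EOA = q_peak sqrt(rho / (2 dp_peak)), with mmHg -> dyn/cm^2
#' conversion. This is the Gorlin-type calibration used to set `a_max` from
#' printed peak values.
#'
#' @param q_peak Peak valve flow (mL/s).
#' @param dp_peak Peak forward pressure difference (mmHg), > 0.
#' @param fluid A [fluid_properties()] object.
#' @return Effective orifice area (cm^2).
#' @export
calibrate_eoa <- function(q_peak, dp_peak, fluid = fluid_properties()) {
  stopifnot(dp_peak > 0)
  q_peak * sqrt(fluid$rho / (2 * dp_peak * DYN_PER_MMHG))
}

#' Quasi-static diastolic membrane state of the closed leaflet
#'
#' Balances the Laplace membrane tension of a spherical leaflet cap against
#' the diastolic transvalvular pressure: solves
#' T(lambda) = dp * cap_radius / 2 with
#' T(lambda) = thickness * sigma_biaxial(lambda) from the equibiaxial
#' incompressible plane-stress response. The root is found by bracketing
#' bisection ([stats::uniroot()]).
#'
#' @param params A [valve_params()] object with a non-`NULL` `material`.
#' @param dp Diastolic pressure load (mmHg), >= 0.
#' @param lambda_max Upper end of the stretch search bracket.
#' @return List with `lambda` (equibiaxial stretch), `tension` (kPa cm),
#'   and `von_mises` (kPa, peak equivalent stress in the membrane).
#' @export
diastolic_membrane_state <- function(params, dp, lambda_max = 2.5) {
  stopifnot(inherits(params, "valve_params"), dp >= 0,
            inherits(params$material, "material_params"))
  if (dp == 0) {
    return(list(lambda = 1, tension = 0, von_mises = 0))
  }
  target <- dp * KPA_PER_MMHG * params$cap_radius / 2  # kPa cm
  g <- function(lam) {
    params$thickness *
      plane_stress_biaxial(params$material, lam, lam)[["sigma11"]] - target
  }
  upper <- lambda_max
  if (g(upper) < 0) {
    stop(sprintf(paste0("no bracketing stretch found in [1, %.3g] for ",
                        "dp = %.3g mmHg; the membrane is too compliant ",
                        "for this search range"), upper, dp))
  }
  lam <- stats::uniroot(g, c(1, upper), tol = 1e-10)$root
  sig <- plane_stress_biaxial(params$material, lam, lam)
  F <- diag(c(lam, lam, 1 / lam^2))
  list(lambda = lam,
       tension = params$thickness * sig[["sigma11"]],
       von_mises = pk1_stress(params$material, F)$von_mises)
}

#' Projected dynamic valve area proxy
#'
#' Maps an opening-fraction trace to a PDVA waveform by proportional scaling:
#' PDVA(t) = a_proj_max * theta(t). This mirrors what the electro-optical
#' subsystem of the pulse duplicator measures, as a surrogate convention.
#'
#' @param theta Numeric vector of opening fractions (one per sample).
#' @inheritParams valve_rate
#' @return Numeric PDVA vector (cm^2) on the same sampling grid.
#' @export
pdva_proxy <- function(theta, params) {
  params$a_proj_max * pmin(pmax(theta, 0), 1)
}
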