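#' Leaflet material parameters
#'
#' Container for the constants of the anisotropic hyperelastic leaflet model:
#' an exponential neo-Hookean matrix term combined with a dispersed collagen
#' fiber reinforcement term of Holzapfel--Gasser--Ogden type, plus a
#' volumetric stabilization term. Stresses are handled internally in kPa;
#' `k1` and `beta_vol` are supplied in MPa, as conventionally printed for
#' fixed-tissue fits, and converted on construction.
#'
#' @param c10 Matrix stiffness (kPa), > 0.
#' @param c01 Matrix exponent (dimensionless), > 0.
#' @param k1 Fiber stiffness (MPa), >= 0. Stored internally in kPa.
#' @param k2 Fiber exponent (dimensionless), >= 0.
#' @param kappa Fiber angle dispersion in [0, 1/3]: 0 = perfectly aligned,
#'   1/3 = isotropic fiber distribution.
#' @param e0 Mean fiber direction in the reference configuration; normalized
#'   to a unit 3-vector.
#' @param beta_vol Volumetric stabilization modulus (MPa). The membrane
#'   computations in this package treat the tissue as exactly incompressible,
#'   so this term is inactive there; it is retained for full 3D deformation
#'   states.
#' @return An object of class `material_params`.
#' @seealso [material_preset()] for the porcine and bovine-pericardial fits.
#' @export
material_params <- function(c10, c01, k1, k2, kappa = 0,
                            e0 = c(1, 0, 0), beta_vol = 14.1) {
  stopifnot(is.numeric(c10), length(c10) == 1L, c10 > 0)
  stopifnot(is.numeric(c01), length(c01) == 1L, c01 > 0)
  stopifnot(is.numeric(k1), length(k1) == 1L, k1 >= 0)
  stopifnot(is.numeric(k2), length(k2) == 1L, k2 >= 0)
  stopifnot(is.numeric(kappa), length(kappa) == 1L,
            kappa >= 0, kappa <= 1 / 3 + 1e-12)
  stopifnot(is.numeric(e0), length(e0) == 3L, any(e0 != 0))
  stopifnot(is.numeric(beta_vol), length(beta_vol) == 1L, beta_vol >= 0)
  structure(list(
    c10 = c10,                 # kPa
    c01 = c01,
    k1 = k1 * 1000,            # kPa (input MPa)
    k1_mpa = k1,
    k2 = k2,
    kappa = min(kappa, 1 / 3),
    e0 = e0 / sqrt(sum(e0^2)),
    beta = beta_vol * 1000,    # kPa (input MPa)
    beta_mpa = beta_vol
  ), class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat("Anisotropic hyperelastic leaflet material\n")
  cat(sprintf("  C10 = %g kPa, C01 = %g\n", x$c10, x$c01))
  cat(sprintf("  k1  = %g MPa, k2 = %g, kappa = %g\n",
              x$k1_mpa, x$k2, x$kappa))
  cat(sprintf("  e0  = (%.4f, %.4f, %.4f), beta = %g MPa\n",
              x$e0[1], x$e0[2], x$e0[3], x$beta_mpa))
  invisible(x)
}

#' Aortic test-section wall parameters
#'
#' Penalty-method description of the (effectively rigid) glass test section:
#' a stiff neo-Hookean energy plus a linear tether force density pulling
#' material points back to their reference positions.
#'
#' @param c_wall Neo-Hookean wall stiffness (kPa), > 0.
#' @param kappa_wall Tether stiffness density (MPa/cm^2), > 0.
#' @return An object of class `wall_params`.
#' @export
wall_params <- function(c_wall = 33.1, kappa_wall = 852) {
  stopifnot(c_wall > 0, kappa_wall > 0)
  structure(list(c_wall = c_wall, kappa_wall = kappa_wall),
            class = "wall_params")
}

#' Kinematic invariants of a deformation gradient
#'
#' Computes the volumetric/isochoric split of a deformation gradient `F`:
#' the Jacobian J = det(F), the modified tensor Fbar = J^(-1/3) F, the
#' modified right Cauchy--Green tensor Cbar = Fbar' Fbar, its first invariant
#' I1bar = tr(Cbar), and the clamped fourth (fiber) invariant
#' I4bar* = max(e0' Cbar e0, 1). The clamp makes the fiber term active in
#' extension but not in compression.
#'
#' @param F 3x3 deformation gradient with positive determinant.
#' @param e0 Mean fiber direction (unit 3-vector; normalized internally).
#' @return An object of class `deformation_state` with fields `F`, `J`,
#'   `Fbar`, `Cbar`, `i1bar`, `i4bar`, `i4bar_star`.
#' @export
compute_invariants <- function(F, e0 = c(1, 0, 0)) {
  F <- as.matrix(F)
  stopifnot(identical(dim(F), c(3L, 3L)), is.numeric(F), all(is.finite(F)))
  J <- det(F)
  if (J <= 0) {
    stop("invalid deformation: det(F) = ", format(J), " is not positive")
  }
  e0 <- e0 / sqrt(sum(e0^2))
  Fbar <- J^(-1 / 3) * F
  Cbar <- crossprod(Fbar)
  i1bar <- sum(diag(Cbar))
  i4bar <- drop(crossprod(e0, Cbar %*% e0))
  structure(list(
    F = F, J = J, Fbar = Fbar, Cbar = Cbar,
    i1bar = i1bar, i4bar = i4bar, i4bar_star = max(i4bar, 1),
    e0 = e0
  ), class = "deformation_state")
}

# Fiber pseudo-invariant argument of the exponential reinforcement term;
# zero at the reference state for any dispersion kappa.
fiber_strain <- function(params, i1bar, i4bar_star) {
  params$kappa * i1bar + (1 - 3 * params$kappa) * i4bar_star - 1
}

# Guards the exponential reinforcement term against overflow, naming the
# invariant that caused it as required for diagnosing runaway deformations.
check_fiber_exponent <- function(params, E, i4bar) {
  if (params$k2 * E^2 > 700) {
    stop(sprintf(paste0(
      "overflow in the fiber reinforcement exponential: k2 * E^2 = %.3g ",
      "with I4bar = %.6g; the fourth invariant is too large for this ",
      "parameter set"), params$k2 * E^2, i4bar))
  }
  invisible(TRUE)
}

#' Strain-energy density of the leaflet model
#'
#' Evaluates W_iso + W_aniso + U:
#' \deqn{W_{iso} = C_{10}\{\exp[C_{01}(\bar I_1 - 3)] - 1\}}
#' \deqn{W_{aniso} = \frac{k_1}{2 k_2}\{\exp[k_2 (\kappa \bar I_1 +
#'   (1 - 3\kappa)\bar I_4^* - 1)^2] - 1\}}
#' \deqn{U = \beta (J \ln J - J + 1)}
#' The anisotropic term is computed with `expm1` so that small fiber
#' exponents (e.g. k2 = 0.001 for the porcine fit) do not suffer
#' cancellation; at k2 = 0 the analytic limit (k1/2) E^2 is used.
#'
#' @param params A [material_params()] object.
#' @param state A `deformation_state` from [compute_invariants()], or a 3x3
#'   deformation gradient (the fiber direction is then taken from `params`).
#' @return Energy density in kPa (dimensionless x stress).
#' @export
strain_energy <- function(params, state) {
  if (!inherits(state, "deformation_state")) {
    state <- compute_invariants(state, params$e0)
  }
  E <- fiber_strain(params, state$i1bar, state$i4bar_star)
  check_fiber_exponent(params, E, state$i4bar)
  w_iso <- params$c10 * expm1(params$c01 * (state$i1bar - 3))
  w_aniso <- if (params$k2 < .Machine$double.eps) {
    0.5 * params$k1 * E^2
  } else {
    params$k1 / (2 * params$k2) * expm1(params$k2 * E^2)
  }
  u_vol <- params$beta * (state$J * log(state$J) - state$J + 1)
  w_iso + w_aniso + u_vol
}

#' First Piola--Kirchhoff stress of the leaflet model
#'
#' Analytic stress P = dPsi/dF of the full strain energy (isochoric +
#' volumetric), with the Cauchy stress sigma = J^-1 P F' and the von Mises
#' equivalent stress of its deviator.
#'
#' @inheritParams strain_energy
#' @param F 3x3 deformation gradient with positive determinant.
#' @return An object of class `stress_result` with fields `pk1`, `cauchy`
#'   (both kPa, 3x3) and `von_mises` (kPa, scalar).
#' @export
pk1_stress <- function(params, F) {
  st <- compute_invariants(F, params$e0)
  E <- fiber_strain(params, st$i1bar, st$i4bar_star)
  check_fiber_exponent(params, E, st$i4bar)

  Finv_t <- t(solve(st$F))
  Jm23 <- st$J^(-2 / 3)
  # dW/dI1bar for the matrix term
  w1 <- params$c10 * params$c01 * exp(params$c01 * (st$i1bar - 3))
  # dW/dE for the fiber term (finite k2 -> 0 limit is k1 * E)
  wE <- params$k1 * E * exp(params$k2 * E^2)

  dI1bar <- 2 * Jm23 * st$F - (2 / 3) * st$i1bar * Finv_t
  P <- (w1 + wE * params$kappa) * dI1bar
  if (st$i4bar > 1) {
    Fe0 <- drop(st$F %*% st$e0)
    dI4bar <- 2 * Jm23 * tcrossprod(Fe0, st$e0) - (2 / 3) * st$i4bar * Finv_t
    P <- P + wE * (1 - 3 * params$kappa) * dI4bar
  }
  P <- P + params$beta * log(st$J) * st$J * Finv_t

  sigma <- (P %*% t(st$F)) / st$J
  sigma <- (sigma + t(sigma)) / 2
  dev <- sigma - diag(mean(diag(sigma)), 3)
  structure(list(
    pk1 = P, cauchy = sigma,
    von_mises = sqrt(1.5 * sum(dev^2))
  ), class = "stress_result")
}

#' @export
print.stress_result <- function(x, ...) {
  cat("Leaflet stress state (kPa)\n")
  cat("  Cauchy:\n")
  print(signif(x$cauchy, 5))
  cat(sprintf("  von Mises: %.5g kPa\n", x$von_mises))
  invisible(x)
}

#' Incompressible plane-stress biaxial response
#'
#' Membrane response used for biaxial-test emulation, parameter fitting and
#' the diastolic leaflet load state: the deformation is the incompressible
#' biaxial state F = diag(lam1, lam2, 1/(lam1 lam2)) with the mean fiber
#' direction rotated in-plane by `fiber_angle`, and the out-of-plane normal
#' stress is eliminated by the incompressibility pressure (sigma_33 = 0).
#'
#' @param params A [material_params()] object (its `e0` is ignored; the
#'   in-plane `fiber_angle` defines the fiber direction here).
#' @param lam1,lam2 In-plane principal stretches, > 0.
#' @param fiber_angle In-plane mean fiber angle from axis 1 (radians).
#' @return Named numeric vector with `sigma11`, `sigma22`, `sigma12` (kPa).
#' @export
plane_stress_biaxial <- function(params, lam1, lam2, fiber_angle = 0) {
  stopifnot(lam1 > 0, lam2 > 0)
  e0 <- c(cos(fiber_angle), sin(fiber_angle), 0)
  p2 <- params
  p2$e0 <- e0
  F <- diag(c(lam1, lam2, 1 / (lam1 * lam2)))
  sigma <- pk1_stress(p2, F)$cauchy
  p <- sigma[3, 3]
  c(sigma11 = sigma[1, 1] - p,
    sigma22 = sigma[2, 2] - p,
    sigma12 = sigma[1, 2])
}

#' Wall tether force density and wall energy
#'
#' The rigid test section is modeled by a penalty: a linear spring force
#' density pulling current positions `chi` back to reference positions `X`,
#' alongside a stiff neo-Hookean wall energy.
#'
#' @param wall A [wall_params()] object.
#' @param X Reference position (cm), numeric 3-vector.
#' @param chi Current position (cm), numeric 3-vector.
#' @return Force density vector `kappa_wall * (X - chi)` (MPa/cm).
#' @export
wall_tether_force <- function(wall, X, chi) {
  stopifnot(inherits(wall, "wall_params"),
            length(X) == length(chi))
  wall$kappa_wall * (X - chi)
}

#' @rdname wall_tether_force
#' @param F 3x3 deformation gradient of the wall material.
#' @return `wall_energy` returns the neo-Hookean wall energy density
#'   (c_wall/2)(I1bar - 3) in kPa.
#' @export
wall_energy <- function(wall, F) {
  st <- compute_invariants(F)
  wall$c_wall / 2 * (st$i1bar - 3)
}
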